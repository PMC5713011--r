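#' Read an ECG signal file
#'
#' Dispatches on `format`: `"csv"` reads the package's CSV signal dialect
#' (see [read_ecg_csv()]), `"wfdb"` reads a WFDB header/signal pair
#' (see [read_ecg_wfdb()]). With `format = "auto"` the extension decides
#' (`.hea` or no extension means WFDB).
#'
#' @param path file path (for WFDB, the header path or the record name
#'   without extension).
#' @param format one of `"auto"`, `"csv"`, `"wfdb"`.
#' @param ... passed to the format-specific reader.
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(file_ext(path))
    format <- if (ext %in% c("csv", "txt")) "csv" else "wfdb"
  }
  switch(format,
         csv  = read_ecg_csv(path, ...),
         wfdb = read_ecg_wfdb(path, ...))
}

file_ext <- function(path) sub(".*\\.", "", basename(path))

#' Read / write the CSV signal dialect
#'
#' The CSV dialect stores one metadata line `# fs=<Hz> t0=<s> units=<unit>`
#' followed by a header row of lead names and one row per sample. Amplitudes
#' are in mV; any other declared unit passes through with a warning.
#' `dec = ","` accepts comma-decimal numbers (e.g. `"33602,99"`), the dialect
#' used by some European exports; fields are then expected to be
#' tab- or semicolon-separated.
#'
#' @param path file path.
#' @param dec decimal separator, `"."` (default) or `","`.
#' @return an [ecg_record()].
#' @export
read_ecg_csv <- function(path, dec = ".") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("CSV signal file must start with a '# fs=... ' metadata line",
         call. = FALSE)
  meta <- parse_meta_line(first)
  if (is.na(meta$fs)) stop("metadata line does not declare fs", call. = FALSE)
  sep <- if (dec == ",") ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          skip = 1L, check.names = FALSE)
  if (!nrow(df)) stop("no samples in file", call. = FALSE)
  if (!is.null(meta$units) && !identical(meta$units, "mV"))
    warning(sprintf("units '%s' are not mV; amplitudes pass through unchanged",
                    meta$units), call. = FALSE)
  ecg_record(as.matrix(df), fs = meta$fs, lead_names = names(df),
             t0 = meta$t0, gaps = meta$gaps)
}

parse_meta_line <- function(line) {
  kv <- regmatches(line, gregexpr("[A-Za-z0-9_]+=[^ ]+", line))[[1]]
  out <- list(fs = NA_real_, t0 = 0, units = NULL, gaps = NULL)
  for (tok in kv) {
    key <- sub("=.*", "", tok)
    val <- sub("^[^=]+=", "", tok)
    if (key == "fs") out$fs <- as.numeric(val)
    else if (key == "t0") out$t0 <- as.numeric(val)
    else if (key == "units") out$units <- val
    else if (key == "gaps" && nzchar(val)) {
      pairs <- strsplit(strsplit(val, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      out$gaps <- do.call(rbind, lapply(pairs, as.numeric))
    }
  }
  if (!is.na(out$fs) && out$fs <= 0) stop("declared fs must be > 0", call. = FALSE)
  out
}

#' @rdname read_ecg_csv
#' @param record an [ecg_record()].
#' @param digits significant digits written (storage precision).
#' @export
write_ecg_csv <- function(record, path, dec = ".", digits = 10) {
  stopifnot(inherits(record, "ecg_record"))
  gap_str <- if (nrow(record$gaps))
    paste0(" gaps=", paste(sprintf("%.6g-%.6g", record$gaps[, 1], record$gaps[, 2]),
                           collapse = ";")) else ""
  meta <- sprintf("# fs=%.10g t0=%.10g units=mV%s", record$fs, record$t0, gap_str)
  sep <- if (dec == ",") ";" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(record$lead_names, collapse = sep), con)
  body <- apply(signif(record$samples, digits), 1L, function(row) {
    row <- format(row, trim = TRUE, scientific = FALSE, digits = digits)
    if (dec == ",") row <- sub(".", ",", row, fixed = TRUE)
    paste(row, collapse = sep)
  })
  writeLines(body, con)
  invisible(path)
}

# --- minimal WFDB (format 16) support ---------------------------------------
# Text header <record>.hea: "name nsig fs nsamp" then one line per signal
# "<file> 16 <gain>(baseline)/mV <adcres> <adczero> <init> <chk> <blk> <name>".
# Signal file: little-endian int16, samples interleaved across leads.
# physical = (adc - baseline) / gain

#' Read / write WFDB records (format 16)
#'
#' A deliberately small reader/writer for the WFDB interchange format:
#' text header plus a single interleaved 16-bit little-endian signal file.
#' Amplitudes are converted to physical units via each signal's gain and
#' baseline. Only format 16 with one signal file per record is supported.
#'
#' @param path record name, with or without the `.hea` extension.
#' @return an [ecg_record()].
#' @export
read_ecg_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop(sprintf("header not found: %s", hea), call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4L) stop("malformed WFDB record line", call. = FALSE)
  nsig <- as.integer(rec[2]); fs <- as.numeric(rec[3]); nsamp <- as.integer(rec[4])
  if (is.na(fs) || fs <= 0) stop("WFDB header declares invalid fs", call. = FALSE)
  sig <- lapply(lines[1L + seq_len(nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  dat <- unique(vapply(sig, `[`, "", 1L))
  if (length(dat) != 1L)
    stop("only single-signal-file WFDB records are supported", call. = FALSE)
  fmt <- vapply(sig, `[`, "", 2L)
  if (!all(fmt == "16")) stop("only WFDB format 16 is supported", call. = FALSE)
  gain_field <- vapply(sig, `[`, "", 3L)
  gain_num <- sub("\\(.*", "", sub("/.*", "", gain_field))
  baseline <- ifelse(grepl("\\(", gain_field),
                     sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field), "0")
  gain <- as.numeric(gain_num); baseline <- as.numeric(baseline)
  gain[is.na(gain) | gain == 0] <- 200  # WFDB default gain (adu/mV)
  lead_names <- vapply(seq_along(sig), function(i) {
    v <- sig[[i]]
    if (length(v) >= 9L) paste(v[9:length(v)], collapse = "_") else paste0("lead", i)
  }, "")
  datpath <- file.path(dirname(hea), dat)
  raw <- readBin(datpath, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  adc <- matrix(raw, ncol = nsig, byrow = TRUE)
  phys <- sweep(sweep(adc, 2L, baseline, "-"), 2L, gain, "/")
  ecg_record(phys, fs = fs, lead_names = lead_names)
}

#' @rdname read_ecg_wfdb
#' @param record an [ecg_record()].
#' @param gain ADC units per mV (storage precision is 1/gain mV).
#' @export
write_ecg_wfdb <- function(record, path, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  path <- sub("\\.hea$", "", path)
  name <- basename(path)
  nsig <- ncol(record$samples); nsamp <- nrow(record$samples)
  adc <- round(record$samples * gain)
  if (any(abs(adc) > 32767))
    stop("amplitudes overflow int16 at this gain; lower `gain`", call. = FALSE)
  hea <- c(sprintf("%s %d %.10g %d", name, nsig, record$fs, nsamp),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
                   name, gain, record$lead_names))
  writeLines(hea, paste0(path, ".hea"))
  writeBin(as.integer(t(adc)), paste0(path, ".dat"), size = 2L,
           endian = "little")
  invisible(path)
}
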