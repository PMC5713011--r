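#' Construct an ECG record
#'
#' An `ecg_record` holds one or more equally sampled leads of an ambulatory
#' ECG, in millivolts, together with the sampling rate, the recording start
#' time and (optionally) intervals during which no signal was stored.
#' Sample `i` (1-based) covers the half-open time interval
#' `[t0 + (i-1)/fs, t0 + i/fs)`.
#'
#' @param samples numeric matrix (samples x leads) or a list/vector of
#'   per-lead numeric series, amplitudes in mV. All leads must have equal
#'   length.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_names character vector of lead identifiers; defaults to
#'   `"lead1"`, `"lead2"`, ...
#' @param t0 recording start time in seconds (recording-relative unless the
#'   source provides an absolute origin).
#' @param gaps optional two-column matrix or list of `c(start_s, end_s)`
#'   intervals, relative to the same clock as `t0`, during which no signal
#'   was stored. Must be disjoint, sorted, and inside the record extent.
#'
#' @return an object of class `ecg_record` with elements `samples` (matrix),
#'   `fs`, `lead_names`, `t0`, `gaps` (n x 2 matrix, possibly 0-row).
#' @export
ecg_record <- function(samples, fs, lead_names = NULL, t0 = 0, gaps = NULL) {
  if (is.list(samples) && !is.data.frame(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) > 1L)
      stop("all leads must have equal length", call. = FALSE)
    if (is.null(lead_names) && !is.null(names(samples)))
      lead_names <- names(samples)
    samples <- do.call(cbind, lapply(samples, as.numeric))
  } else if (is.numeric(samples) && is.null(dim(samples))) {
    samples <- matrix(as.numeric(samples), ncol = 1L)
  } else {
    samples <- as.matrix(samples)
    storage.mode(samples) <- "double"
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  if (is.null(lead_names) && !is.null(colnames(samples)))
    lead_names <- colnames(samples)
  n <- nrow(samples)
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(samples)))
  if (length(lead_names) != ncol(samples))
    stop("lead_names length must match number of leads", call. = FALSE)
  colnames(samples) <- lead_names
  gaps <- normalize_gaps(gaps, t0, t0 + n / fs)
  structure(
    list(samples = samples, fs = fs, lead_names = lead_names,
         t0 = t0, gaps = gaps),
    class = "ecg_record")
}

normalize_gaps <- function(gaps, lo, hi) {
  if (is.null(gaps) || (is.matrix(gaps) && nrow(gaps) == 0L))
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start_s", "end_s"))))
  if (is.list(gaps)) gaps <- do.call(rbind, gaps)
  gaps <- matrix(as.numeric(gaps), ncol = 2L)
  colnames(gaps) <- c("start_s", "end_s")
  gaps <- gaps[order(gaps[, 1L]), , drop = FALSE]
  if (any(gaps[, 2L] <= gaps[, 1L]))
    stop("gap intervals must satisfy start_s < end_s", call. = FALSE)
  if (nrow(gaps) > 1L && any(gaps[-1L, 1L] < gaps[-nrow(gaps), 2L]))
    stop("gap intervals must be disjoint", call. = FALSE)
  if (any(gaps[, 1L] < lo - 1e-9) || any(gaps[, 2L] > hi + 1e-9))
    stop("gap intervals must lie within the record extent", call. = FALSE)
  gaps
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<ecg_record> %d lead(s) [%s], %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              ncol(x$samples), paste(x$lead_names, collapse = ", "),
              n, x$fs, n / x$fs, x$t0))
  if (nrow(x$gaps)) cat(sprintf("  %d stored gap interval(s)\n", nrow(x$gaps)))
  invisible(x)
}

#' Duration of an ECG record in seconds
#' @param record an `ecg_record`.
#' @return duration in seconds (`n / fs`).
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  nrow(record$samples) / record$fs
}

#' Extract one lead from an ECG record
#' @param record an `ecg_record`.
#' @param lead lead name or index.
#' @return numeric vector of sample amplitudes (mV).
#' @export
get_lead <- function(record, lead = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.character(lead)) {
    if (!lead %in% record$lead_names)
      stop(sprintf("lead '%s' not found (have: %s)", lead,
                   paste(record$lead_names, collapse = ", ")), call. = FALSE)
    lead <- match(lead, record$lead_names)
  }
  record$samples[, lead]
}
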