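#' Construct a noise map
#'
#' A noise map is the run-length representation of severity labels over
#' continuous time: sorted, non-overlapping, maximal segments
#' `(start_s, end_s, level)` — adjacent segments always carry different
#' levels — covering the labeled extent minus any declared gaps.
#'
#' @param start_s,end_s,level segment fields (half-open intervals, seconds).
#' @param source which labeling produced the map: `"clinical"` or one of the
#'   quantitative components `"bw"`, `"pli"`, `"sdn"`.
#' @param gaps optional n x 2 matrix of unlabeled intervals.
#' @param merge merge adjacent equal-level segments (default TRUE).
#' @return data frame of class `noise_map` with attributes `source`, `gaps`.
#' @export
noise_map <- function(start_s, end_s, level,
                      source = c("clinical", "bw", "pli", "sdn"),
                      gaps = NULL, merge = TRUE) {
  source <- match.arg(source)
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   level = as.integer(level))
  df <- df[order(df$start_s), , drop = FALSE]
  n <- nrow(df)
  if (n && any(df$end_s <= df$start_s))
    stop("map segments must satisfy start_s < end_s", call. = FALSE)
  if (n > 1L && any(df$start_s[-1L] < df$end_s[-n] - 1e-9))
    stop("map segments overlap", call. = FALSE)
  if (merge && n > 1L) {
    keep <- logical(n); keep[1] <- TRUE
    j <- 1L
    out <- df
    for (i in seq_len(n)[-1L]) {
      if (out$level[j] == df$level[i] &&
          isTRUE(all.equal(out$end_s[j], df$start_s[i], tolerance = 1e-9))) {
        out$end_s[j] <- df$end_s[i]
      } else {
        j <- j + 1L
        out[j, ] <- df[i, ]
      }
    }
    df <- out[seq_len(j), , drop = FALSE]
  }
  rownames(df) <- NULL
  gaps <- normalize_gaps(gaps, -Inf, Inf)
  structure(df, source = source, gaps = gaps,
            class = c("noise_map", "data.frame"))
}

#' @export
print.noise_map <- function(x, ...) {
  cat(sprintf("<noise_map:%s> %d segment(s), %.2f s labeled",
              attr(x, "source"), nrow(x), sum(x$end_s - x$start_s)))
  g <- attr(x, "gaps")
  if (nrow(g)) cat(sprintf(", %d gap(s) (%.2f s)", nrow(g), sum(g[, 2] - g[, 1])))
  cat("\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Build a noise map from a per-sample level series
#'
#' Run-length encodes the series; segment boundaries fall at the times of
#' level changes, using the half-open per-sample convention
#' `[t0 + (i-1)/fs, t0 + i/fs)`.
#'
#' @param levels integer per-sample level series.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @param source map source tag.
#' @return a [noise_map()].
#' @export
map_from_levels <- function(levels, fs, t0 = 0, source = "clinical") {
  if (!length(levels)) stop("levels must be non-empty", call. = FALSE)
  r <- rle(as.integer(levels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  noise_map(t0 + starts / fs, t0 + ends / fs, r$values,
            source = source, merge = FALSE)
}

#' Build a noise map from a segment label track
#'
#' Merges adjacent segments that carry the same label; the time not covered
#' by any segment (relative to the track's overall span) is recorded as
#' gaps.
#'
#' @param track a [label_track()].
#' @param source map source tag.
#' @return a [noise_map()] whose `gaps` attribute holds the uncovered
#'   intervals between segments.
#' @export
map_from_track <- function(track, source = "clinical") {
  stopifnot(inherits(track, "label_track"))
  if (!nrow(track))
    return(noise_map(numeric(0), numeric(0), integer(0), source = source))
  gaps <- NULL
  if (nrow(track) > 1L) {
    lead_start <- track$start_s[-1L]
    prev_end <- track$end_s[-nrow(track)]
    open <- lead_start > prev_end + 1e-9
    if (any(open)) gaps <- cbind(prev_end[open], lead_start[open])
  }
  noise_map(track$start_s, track$end_s, track$label,
            source = source, gaps = gaps)
}

#' Expand a noise map back to a per-sample level series
#'
#' Inverse of [map_from_levels()] for maps whose segment boundaries are
#' sample-aligned.
#'
#' @param map a [noise_map()].
#' @param fs sampling rate (Hz).
#' @return integer vector of per-sample levels spanning the map extent.
#' @export
expand_to_levels <- function(map, fs) {
  stopifnot(inherits(map, "noise_map"))
  if (!nrow(map)) return(integer(0))
  t0 <- map$start_s[1]
  n <- round((map$end_s[nrow(map)] - t0) * fs)
  idx_level <- rep(NA_integer_, n)
  for (i in seq_len(nrow(map))) {
    a <- round((map$start_s[i] - t0) * fs) + 1L
    b <- round((map$end_s[i] - t0) * fs)
    idx_level[a:b] <- map$level[i]
  }
  idx_level
}

#' Per-level labeled durations of a noise map
#' @param map a [noise_map()].
#' @return named numeric vector, seconds per level present.
#' @export
map_level_durations <- function(map) {
  stopifnot(inherits(map, "noise_map"))
  if (!nrow(map)) return(stats::setNames(numeric(0), character(0)))
  tapply(map$end_s - map$start_s, map$level, sum)
}

#' Aggregate a noise map into fixed-duration noise bars
#'
#' Splits map segments at bar boundaries and reports, for every bar, the
#' fraction of the bar's labeled time spent at each severity level. The bar
#' grid is anchored at the map's first labeled instant. A bar lying entirely
#' inside declared gaps (or containing no labeled time) is blank. Bars that
#' are partially labeled are normalized by their labeled duration, so
#' fractions always sum to 1 for non-blank bars, and
#' `fraction x labeled_s` recovers the per-level duration exactly.
#'
#' @param map a [noise_map()].
#' @param bar_s bar duration in seconds (30 for event-recorder profiles,
#'   3600 for multi-day Holter profiles).
#' @param gaps optional n x 2 matrix of unlabeled intervals; defaults to the
#'   map's own `gaps` attribute.
#' @return data frame of class `noise_bars` with columns `bar_index`,
#'   `bar_start_s`, `is_blank`, `labeled_s`, `frac_level0` ... `frac_level4`,
#'   and attribute `bar_s`.
#' @export
build_noise_bars <- function(map, bar_s, gaps = NULL) {
  stopifnot(inherits(map, "noise_map"))
  if (!is.numeric(bar_s) || bar_s <= 0) stop("bar_s must be > 0", call. = FALSE)
  if (is.null(gaps)) gaps <- attr(map, "gaps")
  gaps <- normalize_gaps(gaps, -Inf, Inf)
  if (!nrow(map)) {
    out <- data.frame(bar_index = integer(0), bar_start_s = numeric(0),
                      is_blank = logical(0), labeled_s = numeric(0))
    for (l in 0:4) out[[paste0("frac_level", l)]] <- numeric(0)
    return(structure(out, bar_s = bar_s, class = c("noise_bars", "data.frame")))
  }
  t_start <- map$start_s[1]
  t_end <- max(map$end_s[nrow(map)], if (nrow(gaps)) max(gaps[, 2]) else -Inf)
  nbar <- ceiling((t_end - t_start) / bar_s - 1e-12)
  dur <- matrix(0, nrow = nbar, ncol = 5L)  # levels 0..4
  for (i in seq_len(nrow(map))) {
    s <- map$start_s[i]; e <- map$end_s[i]; lev <- map$level[i] + 1L
    b0 <- floor((s - t_start) / bar_s + 1e-12)
    b1 <- ceiling((e - t_start) / bar_s - 1e-12) - 1L
    for (b in b0:b1) {
      lo <- max(s, t_start + b * bar_s)
      hi <- min(e, t_start + (b + 1) * bar_s)
      if (hi > lo) dur[b + 1L, lev] <- dur[b + 1L, lev] + (hi - lo)
    }
  }
  labeled <- rowSums(dur)
  blank <- labeled <= 1e-12
  frac <- dur
  frac[!blank, ] <- dur[!blank, , drop = FALSE] / labeled[!blank]
  frac[blank, ] <- NA_real_
  out <- data.frame(bar_index = seq_len(nbar),
                    bar_start_s = t_start + (seq_len(nbar) - 1L) * bar_s,
                    is_blank = blank,
                    labeled_s = labeled)
  for (l in 0:4) out[[paste0("frac_level", l)]] <- frac[, l + 1L]
  structure(out, bar_s = bar_s, class = c("noise_bars", "data.frame"))
}

#' Read / write a noise-bar table (CSV)
#'
#' Columns: `bar_index, bar_start_s, is_blank, labeled_s,
#' frac_level0..frac_level4`; blank bars carry empty fraction fields.
#'
#' @param bars a `noise_bars` data frame from [build_noise_bars()].
#' @param path output file.
#' @export
write_noise_bars <- function(bars, path) {
  stopifnot(inherits(bars, "noise_bars"))
  df <- as.data.frame(bars)
  attr(df, "bar_s") <- NULL
  utils::write.csv(cbind(bar_s = attr(bars, "bar_s"), df), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_noise_bars
#' @export
read_noise_bars <- function(path) {
  df <- utils::read.csv(path)
  bar_s <- df$bar_s[1]
  df$bar_s <- NULL
  df$is_blank <- as.logical(df$is_blank)
  structure(df, bar_s = bar_s, class = c("noise_bars", "data.frame"))
}
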