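#' Severity label taxonomy
#'
#' Clinical noise severity levels used throughout the package:
#' \describe{
#'   \item{0 noise-free}{no noise in the segment}
#'   \item{1 low}{P and T waves and QRS complexes readable}
#'   \item{2 moderate}{only QRS complexes reliably identified (>= 3 beats)}
#'   \item{3 hard}{QRS hardly recognizable or unrecognizable}
#'   \item{4 other}{calibration pulses, flat line, or amplifier saturation}
#' }
#' Levels 0-3 are ordered by severity; level 4 is categorical, outside the
#' ordering.
#'
#' @return named integer vector of the five level codes.
#' @export
severity_levels <- function() {
  c("noise-free" = 0L, "low" = 1L, "moderate" = 2L, "hard" = 3L, "other" = 4L)
}

#' Construct a segment label track
#'
#' An ordered set of non-overlapping labeled time segments
#' `(segment_id, start_s, end_s, label)` with half-open `[start_s, end_s)`
#' semantics. Labels are clinical severity codes 0-4.
#'
#' @param start_s,end_s segment boundaries in seconds, `start_s < end_s`.
#' @param label integer severity codes in 0-4.
#' @param segment_id optional integer ids; defaults to order of `start_s`.
#' @return data frame of class `label_track` with columns
#'   `segment_id, start_s, end_s, label`.
#' @export
label_track <- function(start_s, end_s, label, segment_id = NULL) {
  n <- length(start_s)
  stopifnot(length(end_s) == n, length(label) == n)
  label <- as.integer(label)
  if (any(is.na(label)) || any(label < 0L | label > 4L))
    stop("labels must be integers in 0..4", call. = FALSE)
  if (any(end_s <= start_s))
    stop("segments must satisfy start_s < end_s", call. = FALSE)
  if (is.null(segment_id)) segment_id <- seq_len(n)
  df <- data.frame(segment_id = as.integer(segment_id),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   label = label)
  o <- order(df$start_s)
  if (is.unsorted(df$start_s)) df <- df[o, , drop = FALSE]
  if (n > 1L && any(df$start_s[-1L] < df$end_s[-n] - 1e-9))
    stop("segments overlap", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("label_track", "data.frame")
  df
}

#' Read / write a segment label track (TSV)
#'
#' TSV columns: `segment_id`, `start_s`, `end_s`, `label`. Rows that arrive
#' out of order are sorted by `start_s` with a warning; overlapping segments
#' or labels outside 0-4 are validation errors.
#'
#' @param path file path.
#' @return a [label_track()].
#' @export
read_label_track <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("segment_id", "start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop(sprintf("label track must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (is.unsorted(df$start_s))
    warning("label track rows were out of order; sorted by start_s", call. = FALSE)
  label_track(df$start_s, df$end_s, df$label, df$segment_id)
}

#' @rdname read_label_track
#' @param track a [label_track()].
#' @export
write_label_track <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Total labeled duration of a track
#' @param track a [label_track()].
#' @return seconds, the sum of `end_s - start_s` (half-open intervals never
#'   double-count boundaries).
#' @export
track_duration <- function(track) sum(track$end_s - track$start_s)
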