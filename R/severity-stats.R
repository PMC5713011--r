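#' Conditional amplitude histograms by clinical severity
#'
#' Implements the mixture view of the noise amplitude distribution: the
#' marginal density of a quantitative noise amplitude decomposes as the sum
#' over severity levels of the conditional density times the level prior,
#' `p(n) = sum_i p(n | l_i) P(l_i)`. Each amplitude sample is assigned the
#' severity level of the clinical-map segment containing its time; counts
#' are scaled by the sampling period (1/fs) so bin masses are durations in
#' seconds, and priors are level durations over the total labeled duration.
#' Samples not covered by any segment are excluded (their count is
#' reported).
#'
#' @param amplitude non-negative per-sample amplitude series (mV).
#' @param clinical_map a [noise_map()] covering the amplitude's extent.
#' @param fs sampling rate of `amplitude` (Hz).
#' @param bin_edges increasing numeric bin edges (mV); defaults to
#'   Freedman-Diaconis bins on the pooled amplitudes.
#' @param t0 time of the first amplitude sample (s).
#' @return object of class `conditional_histogram`: list with `bin_edges`,
#'   `counts_by_level` (seconds; levels x bins matrix), `priors`,
#'   `n_uncovered`.
#' @export
conditional_histograms <- function(amplitude, clinical_map, fs,
                                   bin_edges = NULL, t0 = NULL) {
  stopifnot(inherits(clinical_map, "noise_map"))
  a <- as.numeric(amplitude)
  if (any(a < 0)) stop("amplitude must be non-negative", call. = FALSE)
  if (is.null(t0)) t0 <- if (nrow(clinical_map)) clinical_map$start_s[1] else 0
  if (is.null(bin_edges)) {
    h <- stats::IQR(a)
    bw <- if (h > 0) 2 * h / length(a)^(1 / 3) else max(a, 1) / 30
    bin_edges <- seq(0, max(a) + bw, by = bw)
  }
  bin_edges <- as.numeric(bin_edges)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  t_mid <- t0 + (seq_along(a) - 0.5) / fs
  seg <- findInterval(t_mid, clinical_map$start_s)
  lev <- rep(NA_integer_, length(a))
  inside <- seg >= 1L & t_mid < clinical_map$end_s[pmax(seg, 1L)]
  lev[inside] <- clinical_map$level[seg[inside]]
  n_uncovered <- sum(!inside)
  if (n_uncovered)
    message(sprintf("%d sample(s) not covered by the clinical map were excluded",
                    n_uncovered))
  keep <- inside
  bins <- cut(a[keep], breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  levels_present <- sort(unique(lev[keep]))
  counts <- t(vapply(levels_present, function(l) {
    tabulate(as.integer(bins)[lev[keep] == l], nbins = length(bin_edges) - 1L)
  }, numeric(length(bin_edges) - 1L))) / fs
  rownames(counts) <- paste0("level", levels_present)
  durs <- map_level_durations(clinical_map)
  priors <- as.numeric(durs[as.character(levels_present)]) / sum(durs)
  names(priors) <- rownames(counts)
  structure(list(bin_edges = bin_edges, counts_by_level = counts,
                 priors = priors, levels = levels_present,
                 n_uncovered = n_uncovered),
            class = "conditional_histogram")
}

#' Marginal histogram from a conditional histogram
#'
#' The per-bin sum over levels of the conditional counts; by construction it
#' equals the histogram of the pooled covered samples exactly.
#'
#' @param ch a `conditional_histogram`.
#' @return numeric vector of per-bin durations (s).
#' @export
marginal_histogram <- function(ch) {
  stopifnot(inherits(ch, "conditional_histogram"))
  colSums(ch$counts_by_level)
}

#' Write a conditional histogram as CSV
#' @param ch a `conditional_histogram`.
#' @param path output file; columns `bin_left, bin_right, level, seconds`.
#' @export
write_conditional_histogram <- function(ch, path) {
  stopifnot(inherits(ch, "conditional_histogram"))
  nb <- length(ch$bin_edges) - 1L
  df <- do.call(rbind, lapply(seq_along(ch$levels), function(i) {
    data.frame(bin_left = ch$bin_edges[-(nb + 1L)],
               bin_right = ch$bin_edges[-1L],
               level = ch$levels[i],
               seconds = ch$counts_by_level[i, ])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-level duration summary of a noise map
#'
#' Totals and percentages of the labeled time spent at each severity level.
#' Durations may also be supplied directly as a named numeric vector
#' (seconds per level), e.g. parsed from reported duration strings with
#' [parse_duration()].
#'
#' @param map a [noise_map()], or a named numeric vector of per-level
#'   durations in seconds (names are level codes).
#' @return data frame of class `duration_summary` with columns `level`,
#'   `seconds`, `percent` (of the labeled total).
#' @export
duration_summary <- function(map) {
  durs <- if (inherits(map, "noise_map")) {
    if (!nrow(map)) stop("empty noise map", call. = FALSE)
    map_level_durations(map)
  } else {
    if (!is.numeric(map) || !length(map))
      stop("supply a noise_map or a named numeric duration vector", call. = FALSE)
    map
  }
  lev <- if (!is.null(names(durs))) names(durs) else as.character(seq_along(durs) - 1L)
  df <- data.frame(level = lev, seconds = as.numeric(durs),
                   percent = 100 * as.numeric(durs) / sum(durs))
  rownames(df) <- NULL
  class(df) <- c("duration_summary", "data.frame")
  df
}

#' Construct a duration-weighted confusion matrix
#'
#' Cross-tabulation of two observers' severity labelings, entries in
#' minutes of labeled time (observer 1 in rows, observer 2 in columns).
#' Any non-negative weights are accepted: Cohen's kappa is invariant to
#' overall scale.
#'
#' @param durations square numeric matrix, entries >= 0, at least 2 classes.
#' @param class_names optional class labels.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(durations, class_names = NULL) {
  m <- as.matrix(durations)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(m < 0)) stop("entries must be non-negative", call. = FALSE)
  if (is.null(class_names))
    class_names <- if (!is.null(rownames(m))) rownames(m)
                   else paste0("class", seq_len(nrow(m)))
  dimnames(m) <- list(class_names, class_names)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Read / write a confusion matrix (CSV)
#'
#' Square CSV with a header row and first column of class names.
#'
#' @param path file path.
#' @return a [confusion_matrix()].
#' @export
read_confusion_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  confusion_matrix(as.matrix(df), class_names = rownames(df))
}

#' @rdname read_confusion_matrix
#' @param m a [confusion_matrix()].
#' @export
write_confusion_matrix <- function(m, path) {
  stopifnot(inherits(m, "confusion_matrix"))
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' Cohen's kappa from a confusion matrix
#'
#' Unweighted chance-corrected agreement,
#' `kappa = (Po - Pe) / (1 - Pe)` with `Po = trace / N` and
#' `Pe = sum(row_i * col_i) / N^2`. Scale-invariant, so entries may be
#' minutes, seconds, or counts.
#'
#' @param m a [confusion_matrix()] or square numeric matrix.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m) || nrow(m) < 2L)
    stop("need a square matrix with at least 2 classes", call. = FALSE)
  N <- sum(m)
  if (N <= 0) stop("confusion matrix total must be > 0", call. = FALSE)
  po <- sum(diag(m)) / N
  pe <- sum(rowSums(m) * colSums(m)) / N^2
  if (abs(1 - pe) < 1e-15)
    stop("kappa undefined: expected agreement Pe = 1 (degenerate margins)",
         call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Merge classes of a confusion matrix
#'
#' Sums rows and columns within each group of the supplied partition;
#' merged class names are joined with a hyphen. Used, e.g., to pool the
#' noise-free and low-noise classes before recomputing kappa.
#'
#' @param m a [confusion_matrix()].
#' @param groups list of integer vectors partitioning `1:nclass`.
#' @return a [confusion_matrix()] with `length(groups)` classes.
#' @export
merge_classes <- function(m, groups) {
  stopifnot(inherits(m, "confusion_matrix"))
  k <- nrow(m)
  idx <- as.integer(sort(unlist(groups)))
  if (!identical(idx, seq_len(k)))
    stop("groups must partition the class indices exactly", call. = FALSE)
  if (length(groups) < 2L)
    stop("merging all classes leaves a single class; kappa undefined", call. = FALSE)
  A <- matrix(0, k, length(groups))
  for (j in seq_along(groups)) A[groups[[j]], j] <- 1
  merged <- t(A) %*% unclass(m) %*% A
  nm <- vapply(groups, function(g) paste(rownames(m)[g], collapse = "-"), "")
  confusion_matrix(merged, class_names = nm)
}
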