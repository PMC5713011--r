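#' @title Quantitative noise estimators
#' @name noise_estimators
#' @description
#' Three per-lead noise components are estimated from the raw signal:
#' baseline wander (BW) as a cubic-spline trend, powerline interference
#' (PLI) as a zero-phase notch-filter residual, and the block-wise
#' standard-deviation noise statistic (SDN) that flags disconnection and
#' saturation-like corruption. Each estimator returns a `noise_estimate`
#' with a per-sample series of the same length as the input lead.
NULL

noise_estimate <- function(component, values, fs) {
  stopifnot(component %in% c("bw", "pli", "sdn"))
  if (!all(is.finite(values)))
    stop("noise estimate contains non-finite values", call. = FALSE)
  structure(list(component = component, values = as.numeric(values), fs = fs),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate:%s> %d samples @ %g Hz, RMS %.4g mV\n",
              x$component, length(x$values), x$fs,
              sqrt(mean(x$values^2))))
  invisible(x)
}

as_lead <- function(lead) {
  if (inherits(lead, "ecg_record")) stop("pass a single lead, not a record")
  as.numeric(lead)
}

#' Estimate baseline wander by cubic-spline trend fitting
#'
#' The lead is divided into non-overlapping windows of `window_s` seconds;
#' each window contributes one spline node at its center, valued at the
#' window median (the median resists QRS spikes). A cubic spline through the
#' nodes, evaluated at every sample, is the baseline-wander series. Outside
#' the span of the nodes the spline is clamped to the first/last node value
#' rather than extrapolated. A trailing partial window shorter than half a
#' window is dropped; otherwise it contributes a node at its own center.
#'
#' @param lead numeric amplitude series (mV).
#' @param fs sampling rate (Hz).
#' @param window_s node-estimation window in seconds (default 0.8).
#' @return a `noise_estimate` with `component = "bw"`.
#' @export
estimate_bw <- function(lead, fs, window_s = 0.8) {
  x <- as_lead(lead)
  n <- length(x)
  w <- max(2L, round(window_s * fs))
  if (n < 3L * w)
    stop(sprintf("signal too short for BW estimation: need >= %d samples (3 windows), have %d",
                 3L * w, n), call. = FALSE)
  starts <- seq(1L, n, by = w)
  ends <- pmin(starts + w - 1L, n)
  len <- ends - starts + 1L
  keep <- len >= w / 2               # drop a too-short trailing window
  starts <- starts[keep]; ends <- ends[keep]
  node_t <- (starts + ends) / 2      # sample index of window center
  node_v <- vapply(seq_along(starts),
                   function(i) stats::median(x[starts[i]:ends[i]]), numeric(1))
  sf <- stats::splinefun(node_t, node_v, method = "fmm")
  idx <- seq_len(n)
  est <- sf(pmin(pmax(idx, node_t[1]), node_t[length(node_t)]))
  noise_estimate("bw", est, fs)
}

# RBJ-cookbook second-order IIR notch; -3 dB bandwidth = f0 / Q
notch_coefficients <- function(f0, fs, bandwidth) {
  w0 <- 2 * pi * f0 / fs
  Q <- f0 / bandwidth
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Estimate powerline interference as a notch-filter residual
#'
#' The lead is filtered with a second-order IIR notch centered at `f0`
#' (-3 dB bandwidth `bandwidth`), applied forward-backward
#' ([signal::filtfilt()]) so the output is zero-phase and the residual is
#' time-aligned with the input. The PLI noise series is
#' `lead - notch_filtered(lead)`.
#'
#' @inheritParams estimate_bw
#' @param f0 notch center frequency in Hz (default 50, European mains).
#' @param bandwidth -3 dB width of the notch in Hz (default 1).
#' @return a `noise_estimate` with `component = "pli"`.
#' @export
estimate_pli <- function(lead, fs, f0 = 50, bandwidth = 1) {
  x <- as_lead(lead)
  if (fs <= 2 * f0)
    stop(sprintf("fs = %g Hz cannot represent a %g Hz notch (need fs > %g)",
                 fs, f0, 2 * f0), call. = FALSE)
  co <- notch_coefficients(f0, fs, bandwidth)
  filtered <- signal::filtfilt(signal::Arma(b = co$b, a = co$a), x)
  noise_estimate("pli", x - filtered, fs)
}

#' Estimate block-wise standard-deviation noise (SDN)
#'
#' The signal's standard deviation is computed in consecutive blocks of
#' `block_s` seconds; every `group` blocks, the mean and standard deviation
#' of those block values are taken, and mean + 2 x sd is assigned as the
#' noise measure of every block in the group. The block-wise series is
#' expanded to per-sample resolution by piecewise-constant interpolation, so
#' the output has the same length as the input. Sample standard deviations
#' (denominator N - 1) are used throughout. A trailing group with fewer than
#' `group` blocks is processed with its actual count when it has at least 2
#' blocks, and merged into the previous group otherwise; trailing samples
#' beyond the last complete block inherit the final block value.
#'
#' @inheritParams estimate_bw
#' @param block_s block length in seconds (default 0.5).
#' @param group number of blocks per statistics group (default 10).
#' @return a `noise_estimate` with `component = "sdn"` (non-negative).
#' @export
estimate_sdn <- function(lead, fs, block_s = 0.5, group = 10L) {
  x <- as_lead(lead)
  n <- length(x)
  bl <- floor(block_s * fs)
  if (bl < 2L)
    stop("block_s * fs must be at least 2 samples", call. = FALSE)
  nb <- n %/% bl
  if (nb < 1L) stop("signal shorter than one SDN block", call. = FALSE)
  stds <- vapply(seq_len(nb),
                 function(i) stats::sd(x[((i - 1L) * bl + 1L):(i * bl)]),
                 numeric(1))
  g_id <- (seq_len(nb) - 1L) %/% group + 1L
  ng <- max(g_id)
  if (ng > 1L && sum(g_id == ng) < 2L) g_id[g_id == ng] <- ng - 1L
  per_block <- numeric(nb)
  for (g in unique(g_id)) {
    s <- stds[g_id == g]
    v <- if (length(s) >= 2L) mean(s) + 2 * stats::sd(s) else s
    per_block[g_id == g] <- v
  }
  values <- rep(per_block, each = bl)
  if (length(values) < n)           # trailing partial block
    values <- c(values, rep(per_block[nb], n - length(values)))
  noise_estimate("sdn", values, fs)
}

#' Naive amplitude of an estimated noise series
#'
#' The absolute value of the estimated instantaneous noise — the quantity
#' that is histogrammed, thresholded and quantized into severity levels.
#'
#' @param estimate a `noise_estimate` or a numeric series.
#' @return non-negative numeric vector (mV).
#' @export
naive_amplitude <- function(estimate) {
  v <- if (inherits(estimate, "noise_estimate")) estimate$values else estimate
  abs(as.numeric(v))
}

#' Decompose a lead into its quantitative noise components
#'
#' Runs the three estimators on one lead of a record under the additive
#' signal model `x = xc + n_bw + n_pli + n_sdn + e`. The residual is
#' `x - bw - pli`: SDN is a block-wise envelope statistic, not an additive
#' waveform, so it is reported but never subtracted.
#'
#' @param record an [ecg_record()].
#' @param lead lead name or index.
#' @param bw_window_s,pli_f0,pli_bandwidth,sdn_block_s,sdn_group estimator
#'   parameters, see the individual estimators.
#' @return list of class `decomposition` with elements `bw`, `pli`, `sdn`
#'   (noise_estimates) and `residual` (numeric).
#' @export
decompose <- function(record, lead = 1L, bw_window_s = 0.8, pli_f0 = 50,
                      pli_bandwidth = 1, sdn_block_s = 0.5, sdn_group = 10L) {
  x <- get_lead(record, lead)
  fs <- record$fs
  bw <- estimate_bw(x, fs, bw_window_s)
  pli <- estimate_pli(x, fs, pli_f0, pli_bandwidth)
  sdn <- estimate_sdn(x, fs, sdn_block_s, sdn_group)
  structure(list(bw = bw, pli = pli, sdn = sdn,
                 residual = x - bw$values - pli$values),
            class = "decomposition")
}

#' Write a noise estimate as CSV
#'
#' Two columns, `time_s` and `value_mV`, one row per sample.
#'
#' @param estimate a `noise_estimate`.
#' @param path output file.
#' @param t0 time of the first sample (s).
#' @export
write_noise_estimate <- function(estimate, path, t0 = 0) {
  stopifnot(inherits(estimate, "noise_estimate"))
  df <- data.frame(time_s = t0 + (seq_along(estimate$values) - 1L) / estimate$fs,
                   value_mV = estimate$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
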