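#' Construct a threshold set for severity quantization
#'
#' Three increasing amplitude thresholds (mV) splitting a non-negative noise
#' amplitude into four levels: noise-free (<= `t_free`), low
#' (`t_free`, `t_mid`], moderate (`t_mid`, `t_hard`], hard (> `t_hard`).
#'
#' @param t_free,t_mid,t_hard thresholds in mV, `0 < t_free < t_mid < t_hard`.
#' @param component which noise component the thresholds apply to
#'   (`"bw"`, `"pli"`, `"sdn"`), informational.
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(t_free, t_mid, t_hard, component = NA_character_) {
  if (!(t_free > 0 && t_free < t_mid && t_mid < t_hard))
    stop("thresholds must satisfy 0 < t_free < t_mid < t_hard", call. = FALSE)
  structure(list(component = component, t_free = t_free, t_mid = t_mid,
                 t_hard = t_hard),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set%s> free <= %.4g < mid <= %.4g < hard <= %.4g mV\n",
              if (is.na(x$component)) "" else paste0(":", x$component),
              x$t_free, x$t_mid, x$t_hard))
  invisible(x)
}

#' Quantize a noise amplitude series into severity levels 0-3
#'
#' Intervals are closed on the left threshold: an amplitude exactly equal to
#' a threshold maps to the lower level. Quantitative quantization never
#' produces level 4 ("other"); that class is only observable from clinical
#' label tracks or synthetic ground truth.
#'
#' @param amplitude non-negative numeric series (mV); use [naive_amplitude()]
#'   on signed noise estimates first.
#' @param thresholds a [threshold_set()].
#' @return integer vector of levels in 0..3, same length as `amplitude`.
#' @export
quantize_levels <- function(amplitude, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  a <- as.numeric(amplitude)
  if (any(a < 0)) stop("amplitude must be non-negative; apply naive_amplitude() first",
                       call. = FALSE)
  (a > thresholds$t_free) + (a > thresholds$t_mid) + (a > thresholds$t_hard)
}

#' Derive quantization thresholds from pooled noise amplitudes
#'
#' The histogram-based rule set operationalized as quantiles of the pooled
#' amplitude distribution: the noise-free threshold contains the near-zero
#' values (`q_free` quantile), the hard threshold isolates the heavy tail
#' (`q_hard` quantile), and the low/moderate boundary sits halfway between
#' the two. Thresholds may instead be set manually with [threshold_set()];
#' this function is the reproducible default.
#'
#' @param amplitudes pooled non-negative amplitude samples (mV), >= 100 values
#'   with nonzero spread.
#' @param q_free quantile for the noise-free threshold (default 0.25).
#' @param q_hard quantile for the hard-noise threshold (default 0.95).
#' @param component informational component tag.
#' @return a [threshold_set()].
#' @export
derive_thresholds <- function(amplitudes, q_free = 0.25, q_hard = 0.95,
                              component = NA_character_) {
  a <- as.numeric(amplitudes)
  if (length(a) < 100L)
    stop("need at least 100 amplitude samples to derive thresholds", call. = FALSE)
  if (any(a < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (stats::sd(a) == 0)
    stop("degenerate (constant) amplitudes: set thresholds manually with threshold_set()",
         call. = FALSE)
  if (!(q_free > 0 && q_free < q_hard && q_hard < 1))
    stop("quantiles must satisfy 0 < q_free < q_hard < 1", call. = FALSE)
  q <- stats::quantile(a, c(q_free, q_hard), names = FALSE)
  if (q[1] <= 0 || q[1] >= q[2])
    stop("derived thresholds are not strictly increasing and positive; set thresholds manually",
         call. = FALSE)
  threshold_set(q[1], (q[1] + q[2]) / 2, q[2], component = component)
}

#' Read / write threshold configuration (YAML)
#'
#' The YAML maps component names to either explicit thresholds
#' `{t_free, t_mid, t_hard}` or quantiles `{q_free, q_hard}` to be applied
#' to pooled amplitudes at run time.
#'
#' @param path YAML file.
#' @return named list: each element either a [threshold_set()] or a list
#'   with `q_free`/`q_hard`.
#' @export
read_threshold_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(stats::setNames(names(cfg), names(cfg)), function(comp) {
    e <- cfg[[comp]]
    if (!is.null(e$t_free))
      threshold_set(e$t_free, e$t_mid, e$t_hard, component = comp)
    else list(q_free = e$q_free %||% 0.25, q_hard = e$q_hard %||% 0.95)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
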