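#' Generate a clean synthetic ECG
#'
#' Template-beat synthesis: each cardiac cycle is the sum of Gaussian bumps
#' for the P wave, the QRS complex (R peak about 1 mV with small Q and S
#' deflections), and the T wave, repeated with mild beat-to-beat RR jitter.
#' The morphology is deliberately simple — adequate for exercising noise
#' estimators, not physiological modelling.
#'
#' @param fs sampling rate in Hz (event recorders typically 200, Holter 128).
#' @param duration_s recording length in seconds.
#' @param hr_bpm mean heart rate, 30-200 beats/min.
#' @param seed integer seed; the output is a deterministic function of
#'   (arguments, seed).
#' @param rr_jitter_sd standard deviation of the RR-interval jitter as a
#'   fraction of the mean RR (default 0.03).
#' @param n_leads number of (identically generated, independently jittered)
#'   leads.
#' @return an [ecg_record()].
#' @export
generate_clean_ecg <- function(fs, duration_s, hr_bpm = 60, seed = 1L,
                               rr_jitter_sd = 0.03, n_leads = 1L) {
  if (hr_bpm < 30 || hr_bpm > 200)
    stop("hr_bpm must be in [30, 200]", call. = FALSE)
  if (fs <= 0 || duration_s <= 0)
    stop("fs and duration_s must be positive", call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  rr <- 60 / hr_bpm
  # Gaussian bump positions/widths/amplitudes within one cycle (s, s, mV)
  waves <- list(P   = c(center = -0.20, width = 0.025, amp = 0.15),
                Q   = c(center = -0.035, width = 0.010, amp = -0.10),
                R   = c(center =  0.00, width = 0.012, amp = 1.00),
                S   = c(center =  0.035, width = 0.010, amp = -0.15),
                T   = c(center =  0.25, width = 0.050, amp = 0.30))
  out <- matrix(0, nrow = n, ncol = n_leads)
  set.seed(seed)
  for (ld in seq_len(n_leads)) {
    x <- numeric(n)
    beat_t <- 0.3
    while (beat_t < duration_s + rr) {
      for (w in waves) {
        c0 <- beat_t + w["center"]
        span <- abs(t - c0) < 6 * w["width"]
        x[span] <- x[span] + w["amp"] * exp(-((t[span] - c0)^2) / (2 * w["width"]^2))
      }
      beat_t <- beat_t + rr * max(0.5, 1 + stats::rnorm(1, 0, rr_jitter_sd))
    }
    out[, ld] <- x
  }
  ecg_record(out, fs = fs,
             lead_names = paste0("lead", seq_len(n_leads)))
}

#' Construct a noise schedule
#'
#' A list of timed noise episodes to inject into a clean recording. Kinds:
#' `bw_drift` (slow sinusoidal baseline drift; magnitude = drift amplitude,
#' mV), `pli_tone` (mains-frequency sinusoid; magnitude = amplitude, mV),
#' `emg_burst` (band-limited white noise; magnitude = noise sd, mV),
#' `flatline`, `saturation`, `calibration_pulse` (replace the signal;
#' magnitude = level / rail / pulse amplitude, mV).
#'
#' @param start_s,end_s episode boundaries (seconds, half-open).
#' @param kind episode kinds from the closed set above.
#' @param magnitude episode magnitudes (mV).
#' @return data frame of class `noise_schedule`.
#' @export
noise_schedule <- function(start_s, end_s, kind, magnitude) {
  kinds <- c("bw_drift", "pli_tone", "emg_burst",
             "flatline", "saturation", "calibration_pulse")
  kind <- as.character(kind)
  if (!all(kind %in% kinds))
    stop(sprintf("unknown episode kind(s): %s",
                 paste(setdiff(kind, kinds), collapse = ", ")), call. = FALSE)
  if (any(end_s <= start_s)) stop("episodes need start_s < end_s", call. = FALSE)
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   kind = kind, magnitude = as.numeric(magnitude))
  df <- df[order(df$start_s), , drop = FALSE]
  repl <- df[df$kind %in% c("flatline", "saturation", "calibration_pulse"), ]
  if (nrow(repl) > 1L &&
      any(repl$start_s[-1L] < repl$end_s[-nrow(repl)] - 1e-9))
    stop("replace-kind episodes (flatline/saturation/calibration) overlap",
         call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("noise_schedule", "data.frame")
  df
}

# Severity implied by an additive episode's magnitude (mV), relative to the
# template amplitudes (R peak 1 mV, P wave 0.15 mV). Constants are an
# operationalization of the qualitative severity definitions, not a claim
# about expert labeling.
additive_severity <- function(magnitude, qrs_amp = 1, p_amp = 0.15) {
  ifelse(magnitude >= 3 * qrs_amp, 3L,
         ifelse(magnitude >= 1 * qrs_amp, 2L,
                ifelse(magnitude >= p_amp, 1L, 0L)))
}

#' Apply a noise schedule to a clean recording
#'
#' Additive kinds (`bw_drift`, `pli_tone`, `emg_burst`) are summed onto
#' every lead; replace kinds (`flatline`, `saturation`,
#' `calibration_pulse`) overwrite the signal in their window. Ground-truth
#' severity labels are assigned per episode: replace kinds are type 4
#' ("other"); additive kinds map by magnitude — at or above 3x the QRS
#' amplitude type 3, 1-3x type 2, at or above the P-wave amplitude type 1,
#' below that type 0. Where episodes overlap, type 4 dominates, then the
#' highest of 0-3.
#'
#' @param record a clean [ecg_record()] (all leads receive the noise).
#' @param schedule a [noise_schedule()] within the record extent.
#' @param seed integer seed for the stochastic noise kinds.
#' @param pli_f0 mains frequency for `pli_tone` episodes (Hz).
#' @return list of class `labeled_synth_recording` with elements `record`
#'   (noisy), `clean` (input), `truth` (a [label_track()] covering the
#'   extent), `schedule`, `seed`.
#' @export
apply_schedule <- function(record, schedule, seed = 1L, pli_f0 = 50) {
  stopifnot(inherits(record, "ecg_record"), inherits(schedule, "noise_schedule"))
  n <- nrow(record$samples)
  fs <- record$fs
  dur <- n / fs
  if (nrow(schedule) && any(schedule$start_s < -1e-9 | schedule$end_s > dur + 1e-9))
    stop("schedule episodes must lie within the record extent", call. = FALSE)
  t <- (seq_len(n) - 1L) / fs
  set.seed(seed)
  noisy <- record$samples
  sample_level <- matrix(0L, nrow = n, ncol = 1L)[, 1L]
  other_mask <- logical(n)
  for (i in seq_len(nrow(schedule))) {
    ep <- schedule[i, ]
    idx <- which(t >= ep$start_s - 1e-12 & t < ep$end_s - 1e-12)
    if (!length(idx)) next
    te <- t[idx] - ep$start_s
    if (ep$kind == "bw_drift") {
      f_drift <- stats::runif(1, 0.15, 0.35)
      phase <- stats::runif(1, 0, 2 * pi)
      add <- ep$magnitude * sin(2 * pi * f_drift * te + phase)
      ramp <- pmin(1, pmin(te, max(te) - te) / 1.0)  # 1 s taper
      noisy[idx, ] <- noisy[idx, ] + add * ramp
    } else if (ep$kind == "pli_tone") {
      add <- ep$magnitude * sin(2 * pi * pli_f0 * te)
      noisy[idx, ] <- noisy[idx, ] + add
    } else if (ep$kind == "emg_burst") {
      for (ld in seq_len(ncol(noisy))) {
        wn <- stats::rnorm(length(idx), 0, ep$magnitude)
        # band-limit to the 15 Hz..0.45*fs EMG-like band
        bp <- signal::butter(2, c(15, 0.45 * fs) / (fs / 2), type = "pass")
        noisy[idx, ld] <- noisy[idx, ld] + signal::filter(bp, wn)
      }
    } else if (ep$kind == "flatline") {
      noisy[idx, ] <- ep$magnitude
      other_mask[idx] <- TRUE
    } else if (ep$kind == "saturation") {
      noisy[idx, ] <- abs(ep$magnitude)
      other_mask[idx] <- TRUE
    } else if (ep$kind == "calibration_pulse") {
      # 1 Hz train of rectangular pulses, 200 ms wide, `magnitude` mV
      pulse <- (te %% 1) < 0.2
      noisy[idx, ] <- ifelse(pulse, ep$magnitude, 0)
      other_mask[idx] <- TRUE
    }
    if (ep$kind %in% c("bw_drift", "pli_tone", "emg_burst")) {
      lev <- additive_severity(ep$magnitude)
      sample_level[idx] <- pmax(sample_level[idx], lev)
    }
  }
  sample_level[other_mask] <- 4L
  truth_map <- map_from_levels(sample_level, fs, t0 = 0)
  truth <- label_track(truth_map$start_s, truth_map$end_s, truth_map$level)
  noisy_rec <- ecg_record(noisy, fs = fs, lead_names = record$lead_names,
                          t0 = record$t0, gaps = record$gaps)
  structure(list(record = noisy_rec, clean = record, truth = truth,
                 schedule = schedule, seed = seed),
            class = "labeled_synth_recording")
}

#' Generate a labeled synthetic recording from a scenario description
#'
#' Convenience wrapper: builds the clean ECG, then applies the schedule.
#' Scenario YAML files carry `fs`, `duration_s`, `hr_bpm`, `seed` and an
#' `episodes` list with `start_s`, `end_s`, `kind`, `magnitude`.
#'
#' @param fs,duration_s,hr_bpm,seed as in [generate_clean_ecg()].
#' @param schedule a [noise_schedule()]; empty by default.
#' @param ... passed to [generate_clean_ecg()].
#' @return a `labeled_synth_recording`.
#' @export
generate_synth_recording <- function(fs, duration_s, hr_bpm = 60, seed = 1L,
                                     schedule = NULL, ...) {
  if (is.null(schedule))
    schedule <- noise_schedule(numeric(0), numeric(0), character(0), numeric(0))
  clean <- generate_clean_ecg(fs, duration_s, hr_bpm, seed = seed, ...)
  apply_schedule(clean, schedule, seed = seed + 1L)
}

#' @rdname generate_synth_recording
#' @param path YAML scenario file.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  eps <- sc$episodes %||% list()
  schedule <- if (length(eps)) {
    noise_schedule(vapply(eps, `[[`, numeric(1), "start_s"),
                   vapply(eps, `[[`, numeric(1), "end_s"),
                   vapply(eps, `[[`, character(1), "kind"),
                   vapply(eps, `[[`, numeric(1), "magnitude"))
  } else NULL
  generate_synth_recording(fs = sc$fs, duration_s = sc$duration_s,
                           hr_bpm = sc$hr_bpm %||% 60,
                           seed = sc$seed %||% 1L, schedule = schedule)
}
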