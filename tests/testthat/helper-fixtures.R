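# Shared fixtures built in code at test time.

fixture_path <- function(name) system.file("extdata", name, package = "ecgnoise")

# Table of inter-observer labeled minutes used by the concordance tests.
load_interobserver_matrix <- function() {
  read_confusion_matrix(fixture_path("interobserver_confusion_minutes.csv"))
}

# Reported per-level duration strings for the event-recorder pool and the
# 7-day Holter recording.
load_duration_strings <- function(which = c("eer", "holter")) {
  which <- match.arg(which)
  f <- fixture_path(sprintf("%s_severity_durations.tsv", which))
  utils::read.table(f, header = TRUE, sep = "\t")
}

# A small noisy synthetic recording shared across tests.
make_test_recording <- function(fs = 200, duration_s = 60, seed = 11L) {
  sched <- noise_schedule(
    start_s  = c(5, 20, 40),
    end_s    = c(15, 30, 50),
    kind     = c("bw_drift", "pli_tone", "emg_burst"),
    magnitude = c(0.8, 0.3, 4))
  generate_synth_recording(fs, duration_s, hr_bpm = 70, seed = seed,
                           schedule = sched)
}
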