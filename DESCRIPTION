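Package: ecgnoise
Title: Noise Quantification and Clinical Severity Mapping for Long-Term ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative noise assessment for ambulatory electrocardiogram
    recordings (event recorders and multi-day Holter). Estimates three noise
    components per lead: baseline wander by cubic-spline trend fitting,
    powerline interference as a zero-phase notch-filter residual, and a
    block-wise standard-deviation noise statistic that flags disconnection
    and saturation-like corruption. Noise amplitudes are quantized into
    clinical severity levels via histogram-derived thresholds, summarised as
    run-length noise maps and normalized fixed-duration noise bars, and
    compared against expert severity labels through conditional amplitude
    histograms, duration summaries, and duration-weighted Cohen's kappa.
    Includes a seeded synthetic ECG generator with scheduled noise episodes
    and ground-truth labels, plus readers and writers for CSV/WFDB signals,
    segment label tracks, and confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
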