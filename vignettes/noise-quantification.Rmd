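---
title: "Quantifying ECG noise and its clinical severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ECG noise and its clinical severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgnoise)
```

## The model

A recorded ECG lead is treated as the additive superposition

$$x(t) = x_c(t) + n_{bw}(t) + n_{pli}(t) + n_{sdn}(t) + e(t)$$

of the noiseless cardiac signal $x_c$, three quantitative noise components
— baseline wander (BW), powerline interference (PLI) and the block-wise
standard-deviation noise statistic (SDN) — and an error term $e$ for
everything else. Two caveats shape the implementation. First, $x_c$ is
unobservable and never estimated; the package quantifies noise, it does not
denoise. Second, SDN is an *envelope statistic* rather than an additive
waveform: its estimator yields a non-negative block-wise magnitude, so the
reported residual of `decompose()` is $x - n_{bw} - n_{pli}$ with SDN
reported alongside but never subtracted. The components are also not
independent in practice — slow drift inflates block standard deviations, so
BW leaks into SDN and vice versa; this is inherent to the definitions, not
an implementation artifact.

Orthogonal to the quantitative view is a five-level clinical severity
taxonomy, defined by what a clinician can still read: 0 noise-free; 1 low
(P, T and QRS readable); 2 moderate (only QRS reliable, at least three
consecutive beats); 3 hard (QRS hardly recognizable); 4 "other"
(calibration pulses, flat line, saturation). Levels 0–3 are ordered; level
4 is categorical. Quantitative quantization can only produce 0–3: flat-line
and saturation episodes *reduce* most amplitude statistics, so "other" is
detectable only from a clinical label track or synthetic ground truth.

## The estimators and their parameters

**Baseline wander** — one spline node per non-overlapping window of
`window_s = 0.8` s, valued at the window *median* and placed at the window
center, with a cubic spline through the nodes evaluated at every sample.
The median is deliberate: a mean-valued node would be dragged upward by
every QRS complex inside the window, whereas the median tracks the
isoelectric level. Outside the span of the nodes the spline is clamped to
the first/last node value — cubic extrapolation at the edges of a short
record can otherwise swing by several millivolts. A trailing partial window
shorter than half a window is dropped; longer ones get a node at their own
center. 0.8 s is below the slowest common heart period (75 bpm at rest),
so each window typically spans one beat.

**Powerline interference** — the residual `x − notch(x)` of a second-order
IIR notch (RBJ-biquad design) centered at `f0 = 50` Hz with a −3 dB
bandwidth of 1 Hz, applied forward–backward (`signal::filtfilt`) so the
residual is zero-phase and time-aligned with the input. A one-pass IIR
notch would phase-shift the residual by up to a quarter cycle near $f_0$,
which matters when episode boundaries are read off the residual envelope.
Because the notch is narrow (quality factor 50), its impulse response rings
for seconds; accuracy assertions therefore exclude the first and last 10%
of samples (on records of a minute or more this leaves the transients well
outside the assessed region). The estimator requires `fs > 2 f0`; both
target rates (200 Hz event recorders, 128 Hz Holter) satisfy this for
50 Hz mains. Note the forward–backward pass applies the notch twice, so
the residual of a pure 50 Hz unit tone has RMS $1/\sqrt2$ rather than 1 —
the estimator localizes and scores mains contamination, it is not a
calibrated amplitude meter at $f_0$.

**SDN** — standard deviations in consecutive `block_s = 0.5` s blocks;
every `group = 10` blocks the mean $m$ and standard deviation $s$ of the
block values are computed and $m + 2s$ assigned to all blocks in the group,
then expanded per-sample by piecewise-constant interpolation. All standard
deviations are sample standard deviations (denominator $N-1$), stated once
and used consistently. A trailing group with at least two blocks is
processed with its actual count; a singleton group is merged into the
previous one; samples beyond the last complete block inherit the final
value, so every estimator preserves series length. SDN is computed on the
raw signal, not a BW-removed one — the overlap between components is
accepted rather than hidden.

All three estimators are positively homogeneous
(`estimate(c·x) = c·estimate(x)` for `c > 0`) and SDN is additionally
translation-invariant; the test suite asserts these as properties over
randomized inputs.

## Thresholds and quantization

The severity thresholds that quantize a noise amplitude into levels 0–3
were, in the framework this package implements, set manually from pooled
amplitude histograms. They are therefore a first-class configurable object
(`threshold_set`) with a reproducible default: `t_free` at the 0.25
quantile of the pooled naive amplitudes (containing the near-zero mass),
`t_hard` at the 0.95 quantile (isolating the heavy tail), and `t_mid`
halfway between the two. The quantiles are configurable and an explicit
manual override is always available; the package does not claim to
reproduce any particular expert's unpublished threshold values. Intervals
are closed on the left threshold (an amplitude exactly equal to a threshold
maps to the lower level) — arbitrary, but fixed and tested. The intended
workflow derives thresholds once from a wide pool (the event-recorder
histograms) and applies them unchanged elsewhere, which the API mirrors:
`derive_thresholds()` returns a value you pass to any number of
`quantize_levels()` calls.

## Time and amplitude characterization

A **noise map** is the run-length encoding of a per-sample level series (or
a merged clinical label track): sorted, maximal, non-overlapping segments
under a half-open `[start, end)` time convention, which makes duration sums
exact — no boundary is ever counted twice. **Noise bars** aggregate a map
into fixed-duration bins (30 s for event-recorder profiles, 3600 s for
Holter) and report the fraction of each bin's *labeled* time per level. A
partial final bar is kept and normalized by its actual labeled duration,
and a bar is blank only when it contains no labeled time at all (e.g.
wholly inside a gap between stored event-recorder segments); both choices
preserve the conservation identity
`Σ_bars fraction_l × labeled_s = duration_l` exactly, which the tests
assert with rational-arithmetic-level tolerance. The bar grid is anchored
at the map's first labeled instant, making bars equivariant under shifts of
the time origin by whole bars.

The amplitude view conditions each noise component's naive amplitude on the
clinical severity label of the containing segment:
$p(n) = \sum_{i=0}^{4} p(n \mid l_i)\,P(l_i)$, with priors equal to level
durations over the labeled total and histogram counts scaled by the
sampling period so bin masses are seconds. Stored counts are always linear;
log scaling is a rendering choice. Default bin edges use Freedman–Diaconis
on the pooled amplitudes, since no canonical binning is prescribed.
Inter-observer agreement uses unweighted Cohen's kappa on duration-weighted
(minutes) confusion matrices; kappa is scale-invariant, so any non-negative
weighting works. Neighbor-class credit schemes are deliberately not
implemented. `merge_classes()` pools classes (typically noise-free with
low-noise) before recomputation.

## The synthetic generator

`generate_clean_ecg()` builds a template-beat ECG: Gaussian bumps for P
(0.15 mV), QRS (R 1 mV with small Q/S deflections) and T (0.3 mV), repeated
with 3% RR jitter. `apply_schedule()` injects timed episodes: additive
baseline drift (0.15–0.35 Hz sinusoid, 1 s amplitude taper), mains tone,
and band-limited (15 Hz to 0.45·fs) Gaussian muscle noise; flat-line,
saturation and 1 Hz/200 ms calibration-pulse episodes *replace* the signal.
Ground-truth labels are assigned by rule: replace kinds are type 4;
additive kinds map by magnitude — ≥ 3× the QRS amplitude type 3, 1–3×
type 2, at or above the P-wave amplitude (0.15 mV) type 1, below it type 0.
These cut-offs operationalize the qualitative severity definitions for
testing purposes; they are configuration constants, not a claim of
equivalence to expert labeling. Everything is a deterministic function of
(configuration, seed).

What the generator does *not* emulate: pathological rhythms, realistic
PQRST morphology variation, electrode-motion transients, colored 1/f
baseline noise, or inter-lead correlation structure. Passing tests on
synthetic data therefore demonstrate that the estimators, quantization and
bookkeeping behave as specified — not that quantitative severity matches
clinical severity on real patients (on real recordings the two are known to
diverge; that divergence is the motivation for the clinical gold standard).

## Numerical choices and test problem sizes

Filter-accuracy assertions trim 10% of samples at each edge (IIR transient
region). The property suite uses 20–60 s records at 200 Hz, Monte-Carlo
bands frozen from larger oracle runs (e.g. the mean SDN of unit Gaussian
noise lies in [1.0, 1.2], frozen after 200-replicate simulation), and a
single 10-minute recording for the end-to-end severity-recovery check: with
three scheduled 30 s hard bursts (5 mV) and thresholds self-derived from
the recording's own pooled SDN amplitudes, at least 80% of in-burst samples
must quantize to level ≥ 2. These sizes keep the default suite in single
digit seconds while leaving wide margins on every assertion (the recovery
fraction is 1.0 across 20 seeds at these settings).

## Known limitations

- The quantitative/clinical threshold matching performed by a human expert
  in the original framework is not algorithmically reproducible; the
  quantile defaults are a transparent stand-in, and manual thresholds are
  the supported path for matching a specific labeling.
- The WFDB support is minimal by design: format 16, single signal file,
  gain/baseline conversion. Anything richer should go through CSV.
- The reported duration-summary fixture shipped in `inst/extdata` embeds
  one internally inconsistent percentage (the five values sum to 102.34%);
  the package reproduces the four self-consistent values exactly and
  reports the honest recomputed value for the fifth.
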