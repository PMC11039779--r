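---
title: "Gabor filter-bank statistical features for EEG classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gabor filter-bank statistical features for EEG classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own science: the model, the
parameters that matter, the design decisions that were genuinely open, and
what the synthetic-cohort tests do and do not establish about real EEG.

## The pipeline

A two-class EEG classification run proceeds in four steps:

1. **Segmentation.** Each recording (channels x samples, with a sampling
   rate `fs`) is cut into consecutive non-overlapping windows of fixed
   duration (30 s and 60 s are the conventional choices at `fs` = 128 Hz).
   Windows start at sample one and a trailing partial window is dropped,
   because the classifier needs fixed-length inputs. No filtering,
   re-referencing or artifact correction is applied: the pipeline is
   defined on the raw signal, and any preprocessing is the caller's
   responsibility.
2. **Filter bank.** Every channel of every window is convolved with each
   complex Gabor kernel
   `g(t) = (2*pi*sigma_t^2)^(-1/2) exp(-t^2/(2*sigma_t^2)) exp(i*2*pi*(fc/fs)*t)`
   and the modulus `|z(t)|` of the response is kept. A Gabor filter is a
   bandpass filter with the best joint time-frequency localization a
   linear filter can have, which is why a small bank of them suffices to
   tile the 1-64 Hz range that contains the canonical EEG bands.
3. **Statistics.** Each (channel, filter) envelope is reduced to four
   numbers: Shannon entropy, standard deviation, skewness, excess
   kurtosis. The feature vector concatenates these channel-major
   (channel, then filter, then statistic), giving
   `n_channels * n_filters * 4` named features per window — 228/304/380
   for 19 channels with the 3/4/5-filter presets.
4. **Selection and classification.** Features are ranked by a per-feature
   Welch t-test or a chi-square association score, both fitted on training
   rows only; an RBF-kernel SVM or k-NN is then scored under stratified
   10-fold cross-validation or a stratified 80:20 split. Accuracy,
   sensitivity (case = positive class) and specificity are computed from
   pooled confusion counts; a ratio with an empty denominator is reported
   as `NA`, never as zero.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fc` per filter | preset (e.g. 12.8/25.6/38.4 Hz) | Hz | tiles 1-64 Hz; must stay below `fs/2` |
| `sigma` per filter | preset (e.g. 10/10/5) | Hz (default reading) | filter bandwidth; see below |
| `truncation_sigmas` | 4 | time-domain sd multiples | Gaussian mass beyond 4 sd is < 1e-4 |
| `entropy_bins` | 256 | bins | histogram resolution of the entropy estimate |
| SVM `cost`, `gamma` | 1, `1/(p * mean var)` | — | standard defaults; data are standardized first |
| k-NN `k` | 5 | neighbours | odd, so binary votes cannot tie |
| `alpha` (t-test mode) | 0.05 | p-value | conventional two-sided threshold |
| `top_k` (chi-square) | half the features | count | the score has no natural threshold |
| `folds` | 10 | — | the conventional CV protocol |
| `train_frac` | 0.8 | — | the 80:20 split protocol |

## Design decisions

### The unit of `sigma`

The bank presets print bare width numbers (10, 12, 5) while the kernel
formula places `sigma` in the time domain. Read as time-domain *samples*
at 128 Hz, a width of 10 samples gives a frequency-domain standard
deviation of `fs/(2*pi*10)` ≈ 2 Hz — three such filters cannot plausibly
cover 1-64 Hz. Read as a frequency-domain standard deviation in Hz, the
same numbers give bandwidths of tens of Hz whose union does span the
range. The package therefore defaults to `sigma_domain = "freq_hz"`
(`sigma_t = fs/(2*pi*sigma)` samples) and keeps `"time_samples"` available
for fidelity experiments. A guard test asserts that the ±2-sigma coverage
of every preset is wider under the default reading than under the
alternative, so the default cannot silently regress.

### The entropy estimator

"Entropy" of a continuous envelope needs an estimator. The package uses
the Shannon entropy (natural log) of the histogram probability mass over
`entropy_bins` equal-width bins spanning the series' own `[min, max]`,
with empty bins contributing zero. 256 bins echoes the 256-level histogram
convention common in the Gabor/LBP feature literature. Using the
per-series range rather than a global one makes the entropy invariant to
positive rescaling of the signal and requires no cohort-level pass;
`entropy_bins` and the implied log base are configurable.

### Moment conventions

Standard deviation uses the `n-1` sample denominator; skewness and excess
kurtosis use central moments with an `n` denominator
(`m3/m2^1.5`, `m4/m2^2 - 3`), the "type 1" textbook definitions, so a
Gaussian envelope has excess kurtosis 0. A zero-variance envelope returns
`(0, 0, 0, 0)` and is flagged rather than propagating `NaN` — degenerate
synthetic inputs (an all-zero channel) stay finite and visible.

### Selection modes

The per-feature t-test defaults to Welch (unequal variances), robust to
unbalanced window counts; the pooled test is available. Because published
post-selection feature counts in this literature vary without a stated
rule, both an `alpha` threshold mode and a fixed `top_k` mode exist, and
every evaluation records the realized count. The chi-square score needs
non-negative inputs, so each feature is min-max scaled to `[0, 1]` on the
training rows before scoring; the score compares class-wise scaled sums
with their expectation under the class priors. Ties break toward larger
`|t|` then lower column index (t-test) or lower index (chi-square), making
selection fully reproducible from the scores.

### Evaluation protocol and the split unit

Standardization (z-scores), selection and the classifier are all fitted
on the training partition of each fold or split and applied unchanged to
the test partition; the result object records per-fold selected features
so this discipline is testable after the fact.

Windows can be split at the *segment* level (each window an independent
unit — the reading most consistent with window-count bookkeeping in this
literature) or at the *subject* level (all windows of a recording stay on
one side). Segment-level splitting lets windows of one subject straddle
train and test; when per-subject characteristics are stable, a classifier
can then recognise the subject rather than the class, inflating accuracy.
The default remains `split_unit = "segment"`, but every segment-mode
report carries a prominent note, and the package's own parameter-recovery
experiments use `split_unit = "subject"`, the design that rules this
leakage out. For the same reason, chance bounds for null experiments are
computed on the number of independent units — subjects, not windows —
since windows of one subject share its band gains and are far from
independent Bernoulli trials.

### Numerical choices

* Kernels are truncated at ±4 time-domain standard deviations (mass
  beyond < 1e-4), forced to odd length with at least 9 taps; a width
  below one sample is refused as numerically degenerate, and `fc >= fs/2`
  is refused as aliasing.
* Convolution is "same"-length with zero-padded boundaries, the kernel
  centre tap aligned on the current sample. Edge transients are *not*
  trimmed by default (nothing in the protocol trims them); a
  `trim_edges` flag removes one kernel half-length per edge when wanted.
* The kernel normalizer is the unit-area Gaussian constant
  `(2*pi*sigma_t^2)^(-1/2)`. Any global constant cancels in the
  scale-invariant statistics (entropy, skewness, kurtosis) and only
  rescales the standard-deviation features linearly.
* The magnitude is taken directly on the complex Gabor response; no
  Hilbert/analytic-signal step is involved.
* All randomness (fold assignment, splits, synthetic cohorts, classifier
  tie-breaks) funnels through integer seeds; identical seeds give
  byte-identical results.

## The synthetic cohort generator

Real clinical recordings are not distributed with the package, so the
generator produces labelled cohorts in the same shape as a typical
childhood-ADHD resting-state dataset: two classes (default 61 case + 60
control), 19 channels named after the 10-20 system, 128 Hz, a
configurable recording length (default 120 s, a realistic resting-state
take yielding four 30 s windows).

Each channel is a sum of band-limited Gaussian noise processes — one per
canonical band (delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma
30-60 Hz), synthesized by FFT spectral shaping with cosine-tapered band
edges — plus a pink `1/f` background (amplitude 0.5) and a white-noise
floor (sd 0.2). Band amplitudes are scaled by per-subject gains drawn
lognormally around class means; the class effect is multiplicative on
amplitude, so band *power* scales with the gain squared (a configured
theta amplitude ratio of 2 appears as roughly a fourfold theta power
ratio, diluted slightly by the background). By default the case class has
`theta_ratio = 2` times the control theta amplitude, the direction of the
elevated-theta marker reported for ADHD.

The between-subject spread (`subject_gain_sd = 0.1`, lognormal sdlog) is
deliberately modest: the generator is a calibration instrument whose
configured 2x effect must remain a *strong* effect — clearly recoverable
by the pipeline — while a zero effect must leave accuracy at chance. Real
cohorts vary considerably more between subjects, which is one reason the
synthetic recovery results say nothing about attainable clinical accuracy.

What the generator deliberately does **not** emulate: event-related
potentials, eye-blink and movement artifacts, non-stationary drifts,
spatial covariance between channels (channels are independent; a mixing
hook exists but defaults to identity), or the actual spectra of any
clinical dataset. Passing recovery tests therefore demonstrate that the
pipeline's machinery is correct and leak-free — not that its accuracy on
clinical data would reach any particular level.

## Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline at sizes a
laptop handles in minutes: oracle checks on 2-channel, 512-sample inputs;
structural identities on 19-channel windows; parameter recovery on
cohorts of 20 + 20 subjects with 120 s recordings and 30 s windows (160
windows, subject-level 10-fold CV), one cohort with a 2x theta effect and
one null cohort. Statistical assertions use a fixed seed, and the null
arm is judged against the 95% binomial chance interval on its 40
independent subjects.

## Known limitations

* Published clinical accuracies for this family of pipelines cannot be
  reproduced or checked here — the data are not packaged, and the
  synthetic cohorts are not a spectral mimic.
* The chi-square score on min-max-scaled continuous features is a ranking
  heuristic, not a calibrated test; its scores have no p-values.
* EDF support covers the plain 16-bit EDF layout with equal sampling
  rates across signals (sufficient for typical scalp EEG exports); EDF+
  annotations, BDF and vendor formats are out of scope.
* No multiple-testing correction is applied in the t-test mode, matching
  the protocol the pipeline models; with hundreds of features and
  `alpha = 0.05`, some selected features are expected false positives.
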