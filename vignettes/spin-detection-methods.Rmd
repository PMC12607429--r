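---
title: "Detecting trained spin alerts from collar IMU data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trained spin alerts from collar IMU data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spindetect` recognises a trained canine signalling behaviour — two
consecutive clockwise 360° body rotations — in six-channel collar IMU
streams (3-axis linear acceleration, 3-axis angular velocity, 50 Hz).
This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the simulator does and does
not emulate, and the design choices made where the design was genuinely
open.

## The detection problem

A spin alert is a short (roughly 1–5.4 s), high-yaw-rate event embedded in
hours of background behaviour. Two features make it tractable from a
collar sensor: the angular-velocity magnitude during rotation dwarfs
ordinary background motion, and the rotation imposes a periodic structure
at the rotation frequency (2 rotations / duration ≈ 0.8 Hz) on the
accelerometer. Two features make it hard: collar-mounted sensors sit with
inconsistent orientation, so individual axes are not comparable across
dogs or days, and events are rare and highly imbalanced across subjects.

The pipeline follows the standard activity-recognition recipe: sliding
windows → per-window features → supervised classification → temporal
aggregation, evaluated both per window and per behavioural event.

## Simulator

The generator (`simulate_study()`) produces labelled multi-subject studies
whose statistical structure matches the motivating cohort, so every
downstream stage is testable without proprietary data.

**Spin kinematics.** A spin's yaw-rate profile is trapezoidal: linear
ramp-up over the first 10% of the event, constant plateau, ramp-down over
the last 10%, with the plateau scaled so the rectangle-rule integral of
yaw rate over the event is *exactly* `rotations × 360°` (720° by
default). The trapezoid is smooth enough to be physically plausible and
simple enough to be analytically checkable; tests assert the 720°
conservation to 1%. Clockwise, viewed from above with the collar z-axis
up, means negative yaw rate; the convention is configurable because
sensor-axis handedness is not standardised. The accelerometer receives a
lateral (centripetal) component at the rotation frequency with the same
trapezoidal envelope, plus a small second harmonic; transverse gyro axes
get 5% quadrature wobble.

**Durations.** Event durations (the complete two-rotation alert) are
truncated-normal on [1.02, 5.42] s with mean 2.58 s. The spread is not
published for the motivating cohort, so the package fixes sd = 0.7 s: the
resulting truncated distribution has mean ≈ 2.60 s and median ≈ 2.57 s,
consistent with the reported mean (2.58 s) and median (2.52 s). Whether
published durations measure one rotation or the full alert is ambiguous
in the source material; the simulator treats them as full-event durations
(the 1.02 s minimum is implausible for two unhurried rotations otherwise)
and the duration distribution is fully configurable.

**Background and distractors.** The negative class would be trivial as
pure sensor noise, so the background mixes rest (noise floor), gait
(~2 Hz periodic acceleration with harmonics and mild body sway) and shake
(~12 Hz Hann-windowed gyro burst) at configurable rates per minute
(defaults 4 and 2). Distractor amplitudes are chosen so that, with sensor
noise switched off, the mean gyro magnitude inside every spin strictly
exceeds that of every spin-free window — the separability dial used by the
acceptance fixtures: at `noise_sd = 0` the heuristic baseline provably has
a perfect threshold.

**Per-subject variability.** Dogs differ; subject-held-out evaluation is
only meaningful if the simulator encodes that. Each subject draws a spin
tempo shift (sd 0.35 s on the mean duration), an activity multiplier on
both noise scales (U(0.6, 1.6)), a shake vigour (U(50, 120) deg/s), and a
random collar-frame rotation (axis uniform, angle up to 25°). The frame
rotation mirrors the real-world reason raw axes are unreliable; it
preserves vector magnitudes, so the separability guarantee survives it.

**Scale.** Defaults produce 8.5 min per subject (≈ 3060 s total across
six subjects, matching the ≈ 3000 s of labelled data in the motivating
study) with per-subject event counts 74/23/16/10/9/3.

**What the simulator does not emulate**: breed- and morphology-specific
gait signatures, long-tailed real-world behaviours (scratching, play,
shaking off water), sensor saturation and dropout, annotation jitter from
human video labelling, and any physiological correlate of seizures.
Passing tests on simulated data therefore demonstrate the pipeline's
correctness and its behaviour under controlled difficulty — not
field-ready detection performance.

## Windowing and labelling

Windows are 2.6 s — 130 samples at 50 Hz, matching the mean event
duration — with a 1.3 s stride (50% overlap); window and stride sample
counts are `round(seconds × rate)`. Windows start at the first sample
and advance while fully inside the stream; the trailing partial window is
dropped rather than padded, keeping feature dimensions fixed. A window is
labelled *spinning* iff at least 50% of its samples lie inside an
annotated spin interval; the rule is inclusive at exactly 50%. Annotated
intervals are half-open `[start, end)` in seconds from recording start.

A consequence worth knowing: a spin shorter than the stride (1.02–1.3 s)
can, with unlucky alignment, produce *no* majority-covered window at all.
Such events are invisible to segment-level recall yet still count at
event level (see below).

## Curated events

Evaluation at the event level uses fixed-length (7.8 s = 3 windows,
yielding 5 strided windows) behaviourally *pure* events: a spin event
contains one or more complete spin intervals and no partial spin at its
boundaries; a non-spin event overlaps no spin whatsoever. Spin events are
centred on their interval when purity allows, otherwise shifted to an
onset- or offset-anchored placement, and dropped when no pure placement
exists (crowded recordings lose some events; the count is logged).
Non-spin events tile the spin-free stretches with a seeded random offset.
Event spans are snapped to the sample grid so every event slices to the
same number of samples. All train/test splitting is event-based
(stratified 80/20) or subject-based (LODO), so no behavioural occurrence
can span both sides; `leakage_audit()` verifies this on every report.

## Features and selection

Each window yields 48 features: {mean, population SD, range, dominant
frequency, spectral energy, spectral entropy} × {6 raw channels,
accelerometer magnitude, gyroscope magnitude}. The magnitude traces are
included because they are orientation-invariant — the only features that
transfer freely across collar placements — and because the heuristic
baseline is defined on gyro magnitude. Spectral estimates use a single
untapered periodogram of the 130-sample window; Welch averaging would
trade already-scarce frequency resolution (bin width 0.38 Hz) for
variance reduction the downstream models do not need. The DC bin is
excluded from dominant frequency, energy and entropy so the spectral
features are not redundant with the mean (the collinearity filter would
otherwise discard one of the pair arbitrarily). Degenerate (constant)
traces return dominant frequency 0 and entropy 0, never NaN. Entropy is
Shannon entropy (base 2) of the normalised non-DC power spectrum — the
spectral reading of "frequency-domain entropy"; sample entropy is a
different statistic and is out of scope.

Selection runs in a fixed order on training rows only:

1. **Variance filter** — population variance < 0.1 (raw feature scale)
   dropped. The threshold is on raw values by construction, so it mostly
   removes quasi-constant features (e.g. accelerometer means under
   gravity are unaffected).
2. **Collinearity filter** — scanning pairs in schema order, the later
   feature of any pair with |Pearson r| > 0.95 is dropped; keeping the
   earlier feature makes the rule deterministic.
3. **Univariate F-test** — survivors are ranked by the two-group one-way
   ANOVA F statistic against the window label; the top 20 are kept (ties
   broken by schema order). Zero within-group variance with non-zero
   between-group spread ranks as +Inf.

The order matters (a low-variance feature removed at stage 1 can no
longer shadow its correlated partner at stage 2) and is pinned by a
regression test. The fitted `selection_report` is a stateless transform:
applying it never refits, and it serialises to JSON.

## Models

The **heuristic baseline** declares a window spinning iff its mean gyro
magnitude strictly exceeds a threshold. The threshold is tuned on
training data only, by exhaustive search over the midpoints between
consecutive sorted distinct training values (±Inf sentinels included),
maximising spin-class F1 — the headline metric, making the baseline as
strong as a single threshold can be. Ties break toward the larger
threshold: fewer false alarms at equal F1.

Four supervised families run behind one fit/predict contract, using the
standard R engines:

| family | engine | defaults |
|---|---|---|
| `random_forest` | randomForest | 100 trees |
| `svm` | e1071, RBF kernel | cost 1, gamma 1/p; margin as score |
| `naive_bayes` | e1071, Gaussian | variance floor `sqrt(1e-9 × max var)` |
| `logistic` | glmnet ridge | alpha 0, lambda 1/n |

Hyperparameters for the original study are unreported, so these defaults
are ordinary textbook settings, exposed in `classifier_spec()` and *not*
validated against the original; reproduction of its tables to the decimal
is not expected. Ridge (rather than unpenalised) logistic regression
keeps coefficients finite on separable data. All stochastic fitting is
seeded; standardisation statistics are computed from training rows only.

Standardisation defaults to on for every family except the tree ensemble
(invariant to monotone rescaling). Including the Gaussian model is
deliberate: its variance-smoothing floor is shared across features, and on
raw scales — where spectral energy is ~10⁶ times larger than spectral
entropy — the floor is dominated by the largest feature variance, leaving
small-scale features effectively unsmoothed. Z-scoring makes the
smoothing uniform; empirically it removes sporadic false positives on
noiseless backgrounds and improves subject-held-out F1 on noisy data. A
Gaussian density floor of 1e-300 is applied at prediction so windows far
from both classes compare by their informative features instead of tying
at log(0). Class imbalance is left unweighted by default (the motivating
protocol describes none).

## Evaluation

Segment-level metrics are accuracy, spin-class F1
(`2TP/(2TP+FP+FN)`), and ROC-AUC computed as the mid-rank (Wilcoxon)
statistic — exactly the trapezoidal ROC integral, with ties handled by
mid-ranks; single-class truth reports AUC as absent, not NaN. All ratio
metrics are recomputable from the stored confusion counts.

Event-level evaluation applies the OR rule: an event is predicted *spin*
iff at least one of its five windows is predicted positive; the event
score is the maximum window score. Two forms of the OR guarantee are
distinguished deliberately. The exact form — event false negatives are
precisely the spin events whose every window was predicted negative —
holds by construction and is asserted. The popular reading "event
sensitivity ≥ segment sensitivity" is *not* a theorem: spin events with
no majority-covered window (spins shorter than the stride) enter the
event denominator but not the segment denominator, and measurably
reverse the inequality in crowded simulations. The package's tests
therefore assert dominance over the events whose spin is visible at
window level, the regime the rule actually governs.

Protocols: `within_subject_random` (pooled windows, stratified random
split — permits subject and event overlap by design, as the optimistic
reference point), `event_stratified_8020`, `lodo_single_holdout` (one
named dog held out; the motivating study used Rosie, whose data is ≈ 20%
of the cohort), and `lodo_full_cv` (each dog in turn; pooled micro
confusion as the headline aggregate, per-fold results retained). Both
LODO variants exist because the motivating study reports both a single
hold-out and a pooled cross-validation without linking tables to
protocols. The within-subject split ratio is 80/20, stratified by window
label, seeded. Folds whose training data collapse to one class are
skipped with a warning and recorded. Event-level results are reported
for event-based and LODO protocols; the random-window split has no event
corpus, so its report carries segment metrics only.

## Problem sizes and runtime

The test-suite and acceptance computations use the default cohort
(six subjects × 8.5 min at 50 Hz ≈ 2350 windows, 339 curated events) for
the realistic checks, and smaller two/three-subject studies (2–3 min per
subject) for unit-level properties; the full suite runs in about half a
minute, and `scripts/acceptance.R` in about the same. These sizes give
Monte-Carlo error well below the asserted tolerances (e.g. duration-mean
checks use 10 000 sampler draws).

## Known limitations

- Simulated background is a three-behaviour mixture; real negative
  classes are richer, so absolute metrics here overstate field
  performance. The direction of model comparisons (data-driven models
  beating the magnitude threshold under LODO) is the transferable result.
- The Gaussian NB and SVM defaults are unvalidated against the motivating
  study's unreported settings.
- Spins shorter than the stride are structurally hard for the 50%
  labelling rule; a shorter stride or a lower label fraction (both
  configurable) trades compute and false alarms for visibility.
- No real-time/streaming segmentation, no probability calibration, no
  statistical tests between models.
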