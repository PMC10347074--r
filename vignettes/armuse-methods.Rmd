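---
title: "Quantifying functional upper-limb use from bilateral wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying functional upper-limb use from bilateral wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-reported questionnaires such as the QuickDASH capture how a person
perceives her upper-limb function, but not what her arms actually do during
daily life. Wrist-worn accelerometers promise an objective complement, yet
raw acceleration cannot tell *functional* arm use (task-specific movement:
reaching, manipulating objects, making a bed) from *non-functional*
movement (arm swing while walking, fidgeting during conversation). The
standard field method — activity counts with a per-second threshold —
detects *any* movement and is known to overestimate functional use, because
arm swing and incidental movement cross the counts threshold just as task
movement does.

`armuse` implements, as a reusable and fully tested pipeline, the
validation chain for comparing two estimation routes against
video-annotation ground truth on home recordings:

1. a **counts-threshold baseline**: raw 30 Hz acceleration converted to
   1-s activity counts, with a second counted "active" when the vector
   magnitude of the axis counts exceeds 1;
2. a **machine-learning route**: 4-s epoch features (means and variances
   per axis; mean, variance, minimum, maximum and Shannon entropy of the
   acceleration norm) classified functional / non-functional by a random
   forest.

Because the original recordings of the motivating cohort are not publicly
available, the per-participant summary tables of that cohort ship as
plain-CSV fixtures (`cohort_demographics_table()`, `cohort_metrics_table()`,
`cohort_use_table()`), and a synthetic-session generator reproduces the
study conditions so that the full chain — synchronization, trimming,
annotation epoching, both estimation routes, evaluation — is executable
and testable end to end.

## The processing chain and its assumptions

### Axis convention and input

Signals are tri-axial, in g, 30 Hz, one stream per wrist, interchanged as
CSV (`time,x,y,z`). Sensor axes are remapped to an anatomical frame by a
signed permutation (configurable *mounting map*): x vertical along the
forearm (cranial positive), y medio-lateral (medial positive on the right
hand, lateral on the left — the two wrists mirror each other), z
anterior–posterior. A signed permutation preserves the per-sample
Euclidean norm exactly, which both estimation routes depend on.

### Synchronization and trimming

Sessions are bracketed by a *calibration movement*: 3–5 fast arm flexions
performed in camera view. `detect_calibration()` high-passes the
acceleration norm at 0.5 Hz (removing gravity), thresholds at 1.5 g, and
clusters threshold crossings (gaps < 0.25 s within a burst, < 3 s between
bursts of one event). The inter-sensor clock lag is the argmax of the
normalized cross-correlation of the high-passed norms over ±2 s at sample
resolution, evaluated in a window around the first calibration event; a
second estimate in the last event's window is reported as *spot-check
drift* but — deliberately — no drift correction is applied. Everything
before the first and after the second calibration event is discarded, and
all epoch grids are anchored at the trim start (no sliding windows; no
offset search, since none is defined by the protocol).

The cross-correlation assumes the calibration bursts are simultaneous on
both wrists, which the protocol guarantees (both arms flex together). A
periodic burst pattern can in principle alias the lag estimate by one
burst period; with lags bounded by ±2 s and a 1.4 s burst spacing the
full-pattern alignment dominates in practice, and the estimator flags a
peak sitting on the search boundary.

### Annotation epochs

Frame-level annotations (25 fps) use three categories: 0 unknown
(including the calibration itself), 1 non-functional, 2 functional. 4-s
epochs (100 frames) take the label of a **strict majority** (> 50 %) of
frames; with no strict majority the epoch is *mixed*. Unknown epochs are
always discarded. How mixed epochs entered the original evaluation is not
documented; the default policy here excludes them from both training and
scoring (keeping the two symmetric), with `as_functional` /
`as_nonfunctional` available for sensitivity analyses. Functional minutes
are epochs × 4 / 60.

### Counts baseline

The counts conversion follows the published open-source 30 Hz chain: per
axis, a fixed band-pass IIR filter (pass band roughly 0.29–1.63 Hz, the
published 21-term coefficients with gain 0.965), decimation to 10 Hz,
clipping at ±2.13 g, rectification, a 0.068 g deadband, quantisation to
0.0164 g resolution (floor), and summation over the epoch (1 s). The
filter is applied from a steady state (the input is conceptually preceded
by its first sample), so a gravity-only signal produces exactly zero
counts rather than a start-up transient. The filter coefficients and
constants are used verbatim; nothing is re-tuned. An epoch is *active*
when the Euclidean norm of its three axis counts exceeds the threshold
(default 1); per-axis OR logic is available as a configuration switch
because the original description does not say which convention was used.

### Feature extraction and classifier

Signals are spline-resampled from 30 to 50 Hz (cubic splines per axis,
`round(n * 5/3)` output samples; a pure in-band sine is reproduced with
< 1 % amplitude error, and polynomials up to cubic exactly). Eleven
features per 4-s epoch (200 samples): mean and variance per axis, and
mean, variance, minimum, maximum and Shannon entropy of the per-sample
norm. Variances are population variances (divide by *n*) — the convention
is unspecified upstream, so one was fixed and documented. Entropy uses a
16-bin histogram over the epoch's own norm range (probabilities = bin
fractions, 0·log 0 ≡ 0, base 2), making it scale-free per epoch and
bounded by log2(16) = 4 bits; the bin count is exposed because no
estimator is specified upstream. Min–max scaling is fitted on the
training corpus only and persisted inside the model bundle; later data
are clipped into [0, 1] so prediction-time inputs cannot leak their own
range.

The classifier is a retrainable surrogate for the original pre-trained
laboratory model, whose weights were never published: a random forest
(100 trees, unlimited depth, fixed seed) by default, with a single CART
tree offered because the source material describes the model both ways.
No class re-weighting is applied by default (the original work reports an
unbalanced data set but no rebalancing); class weights are exposed as an
option. The model bundle stores the scaler, the frozen feature-order
signature (prediction refuses mismatched column order), and the training
seed.

### Evaluation

With functional as the positive class: accuracy, recall TP/(TP+FN),
specificity TN/(TN+FP), precision TP/(TP+FP), and f1 as the harmonic mean
of precision and recall. Zero-denominator metrics are reported as 0 with
an explicit degenerate flag instead of NaN, keeping cohort averages
well-defined while preserving auditability. Use summaries report total
functional minutes and the fraction of the trimmed session functionally
active, per method; cohort mean differences are mean ± SD over
participants of (method − ground truth). The Spearman correlation is the
tie-corrected form (Pearson on mid-ranks) with a two-sided t-approximation
p-value at n = 10 — an exact permutation distribution under ties is
ambiguous and no method is named upstream.

## The synthetic-session generator

The generator emulates the home protocol: a calibration block, then four
activities of daily living each preceded by walking and followed by
seated conversation, a final walk, and a closing calibration. The default
schedule (270 s per task, 60 s walks and sits, 12 s calibrations) gives a
≈ 27-minute session, in line with the ≈ 25-minute average monitoring
duration of the motivating cohort; cohort experiments default to 10
sessions (6 training / 4 test, split by session).

Signal model, per activity (all on top of a unit gravity vector on the
anatomical x axis, with 0.02 g Gaussian sensor noise):

* **Calibration** — 3–5 rectangular flexion bursts of 2.5–3 g on the
  vertical axis, 0.4 s long, 1.4 s apart, simultaneous on both wrists. A
  fast flexion genuinely exceeds 2 g; amplitudes much below that are
  attenuated under the 1.5 g detection threshold by the 0.5 Hz high-pass.
* **Walking** — a 0.9–1.1 Hz sinusoid of 0.12–0.18 g on the
  anterior–posterior axis, antiphase between arms.
* **Functional bouts** — band-limited (0.5–3 Hz) noise on all three axes.
  The amplitude follows a slowly varying envelope over 0.3–0.8 g
  (sub-tasks differ in vigour) and a movement/hold gate (moving 4–10 s,
  still 0.3–1 s): a task is annotated functional end to end by context,
  yet the wrist is briefly still within it. Bouts are correlated between
  wrists (shared component, weight 0.8) because the emulated tasks are
  largely bimanual.
* **Seated conversation** — sparse incidental movements (default one per
  ≈ 20 s per arm, 3–8 s long, independent per arm) drawn from the *same*
  0.3–0.8 g amplitude distribution as task movement. This is the central
  modelling choice: incidental movement is kinematically indistinguishable
  from task-specific movement and only the video context separates them,
  which is exactly why accelerometer-only methods overestimate functional
  time. The rate is a config field (`incidental_rate_hz`); zero gives
  motionless sitting, the case used for the exact-gravity contract tests.

The right sensor's stream is delayed by a configurable clock offset
(rounded to a whole sample, padded with resting samples), which the
synchronizer must recover. One cohort seed fans out deterministically to
per-session seeds (seed + session index), and every session is a pure
function of its config.

**What the generator does not emulate:** biomechanically realistic limb
kinematics or orientation change (gravity stays on one axis outside
movement), impaired versus unimpaired arms, annotator disagreement or
frame-level annotation noise, sensor clock *drift* within a session, and
the unconstrained variety of real homes. Consequently, passing the
synthetic end-to-end properties shows that the chain is implemented
coherently and reproduces the *structure* of the published findings (the
overestimation ordering counts ≥ classifier ≥ truth, high recall with
imperfect specificity, exact lag recovery); it does not show that the
surrogate classifier would reach any particular accuracy on real
recordings. No amplitude or spectral characterisation of the original
activities was ever published; the generator's parameters are stand-ins
chosen for plausibility, not estimates.

## Numerical choices and degenerate inputs

* Counts filtering uses a 30 s first-sample pre-pad to realize the steady
  state; the same convention is used by the frozen reference fixture.
* Epoch grids: trailing partial epochs (fewer than 200 samples / 100
  frames / 10 counts samples) are dropped.
* Entropy of a constant epoch is 0 (zero range short-circuits the
  histogram); a min–max column with zero fitted range maps to 0.
* Ties in the majority rule (exactly 50/50) are *mixed*, not functional.
* Lag search at the window edge sets an `at_boundary` flag rather than
  failing; flat windows (zero variance of the raw norm) are an error.
* Block boundaries are rounded to whole samples/frames via cumulative
  rounding, conserving per-block counts within one sample.

## Problem sizes used by the shipped experiments

The packaged validation experiment and the acceptance checks simulate 10
sessions of the default ≈ 27-minute schedule at 30 Hz (≈ 49 000 samples
per wrist per session), train on 6 sessions and evaluate on 4 (≈ 1 600
test epochs per run after majority labelling). Unit tests use shorter
schedules of the same structure. These sizes were chosen to match the
motivating cohort (10 participants, ≈ 25 min each) while keeping a full
run in the order of seconds.

## Known limitations

* The classifier is a surrogate trained on synthetic data; its absolute
  accuracy numbers are not comparable to the published per-participant
  accuracies, which came from a lab-pretrained model applied to real
  recordings (those recordings are unavailable).
* The counts chain implements the published 30 Hz algorithm; other sample
  rates would require the up/downsampling front-end of the full published
  pipeline and are rejected rather than approximated.
* The published per-participant table itself contains one participant-side
  where the classifier's percentage exceeds the counts baseline's; the
  strict ordering is therefore asserted only where it actually holds
  (see the cohort-table tests).
* Spot-check drift is reported, never corrected, mirroring the protocol's
  silence on correction.
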