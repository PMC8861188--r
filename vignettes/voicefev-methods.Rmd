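---
title: "Methods: predicting lung function from voice acoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting lung function from voice acoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spirometry requires a forced manoeuvre and equipment; speech does not. In
obstructed airways, speaking is interrupted more often by audible breaths,
breaths become louder relative to speech, and the interval between breaths
shortens. `voicefev` operationalises that observation as a pipeline from a
~30 s voice recording to three predictions about lung function, measured as
FEV1 percent of predicted (FEV1%):

1. a regression estimate of FEV1%,
2. an ordinal severity grade, and
3. a binary normal/abnormal call (normal ⇔ FEV1% > 80).

The pipeline has four stages: frame-level acoustic features → threshold
based breath/speech segmentation → a 23-feature recording vector (+ sex,
height, weight) → three model families (linear, random forest, RBF-kernel
SVM) under balanced train/test partitioning and seeded 10-fold
cross-validation.

Clinical voice corpora with paired spirometry are not generally
redistributable, so the package ships a synthetic-cohort generator with a
*documented, planted* FEV1%→acoustics link and ground-truth segment labels.
Every downstream stage is tested against that known truth.

## The synthetic cohort

`generative_params()` fixes the study conditions. One recording alternates
speech spans (harmonic source, 12 harmonics with 1/h amplitudes, random
phases, slow amplitude modulation, target RMS 0.2) with breath spans
(broadband Gaussian noise), starting with speech, until 30 s at 22050 Hz
are filled.

Two mechanisms carry the signal, both driven by the recording's FEV1% plus
Gaussian noise (`noise_sd`, default 2 FEV1% points — the irreducible error
of any acoustics-based predictor on these data):

* **Breath gain.** Breath RMS is `breath_rms * (1 + breath_gain_slope *
  (100 - FEV1%))` with `breath_rms = 0.03` and slope `0.012` per point:
  a subject at FEV1% 60 breathes ~1.5× louder than at 100, while speech
  RMS stays fixed, keeping the speech/breath RMS ratio above 3 across the
  whole FEV1% range so segmentation remains a threshold problem rather
  than a detection problem.
* **Cycle shortening.** Each speech span's duration is
  `U(2, 5) + cycle_slope * (FEV1% - 100)` seconds (slope `0.02` s/point,
  floored at 1 s), so lower FEV1% yields shorter speech spans, shorter
  breath-onset intervals and more breaths per recording.

Cohort FEV1% values come from a two-component truncated-normal mixture:
N(100, 8) on (80, 125] for normal lung function and N(70, 8) on (50, 80]
for abnormal, with the normal count fixed at `round(0.7214 * n)`. A single
truncated normal cannot simultaneously put its mode near 100, leave no
mass at or below 50, and keep only ~72% of samples above 80 — the mixture
satisfies all three by construction, and incidentally places ~3% of
samples below FEV1% 60, matching the sparse moderate-to-severe tail such
cohorts show. Values are dealt to subjects in contiguous blocks and sorted
decreasing within subject, emulating repeated recordings under a
progressive bronchial challenge; subject identity is deliberately *not*
used by the models (the split unit is the recording — see below).

What the generator does **not** emulate: phonetic content, coarticulation,
room acoustics, microphone response, non-breath pauses, or between-subject
vocal-tract differences beyond f0. Passing tests therefore demonstrate
that the pipeline's machinery is correct and can recover a planted signal
at realistic noise levels; they do not certify clinical performance on
real voice data.

## Frame-level features

All features live on a shared grid (`frame_grid()`: 2048-sample Hann
frames, 512-sample hop, 22050 Hz; ~93 ms / ~23 ms). The waveform is
centre-padded with zeros so frame *i* is centred at `i·hop/sr` seconds.
Conventions, chosen to match the common toolkit definitions:

* RMS, mean amplitude and zero-crossing rate are computed on unwindowed
  frames; ZCR counts strict sign changes over `frame_length - 1` pairs.
* Centroid, bandwidth and roll-off (85%/95%) use **magnitude** spectra;
  flatness uses the **power** spectrum (geometric/arithmetic mean ratio).
* Spectral contrast is the mean over six octave bands above 200 Hz of the
  top-α minus bottom-α mean dB magnitude (α = 0.02, at least one bin).
* An amplitude floor ε = 1e-10 guards all logarithms; an all-zero frame
  yields centroid = bandwidth = roll-off = 0 and flatness = 1.

Every spectral quantity is testable against a dense O(N²) DFT oracle; the
suite holds agreement to relative error below 1e-6.

## Segmentation

Five features discriminate breath from speech frames: spectral contrast,
roll-off at 95%, RMS, bandwidth, and mean amplitude. On labelled exemplar
frames (by default the first five recordings of a cohort, labelled by
ground truth or by hand), `calibrate_thresholds()` places one threshold
per feature at the midpoint of the two class *medians* — medians, because
the amplitude features are heavy-tailed — and records which side breath
falls on. A feature with coincident medians is dropped with a warning;
fewer than three usable rules aborts calibration.

`classify_frames()` labels a frame breath when at least 3 of the 5 rules
vote breath. A majority vote degrades gracefully when a rule is excluded
and is robust to one noisy feature; requiring all five is available via
`min_votes = 5`. The vote is monotone by construction.

`frames_to_segments()` median-filters the labels (width 5 frames), then
absorbs opposite-kind runs shorter than 100 ms and merges remaining runs
shorter than 150 ms, yielding alternating segments that exactly partition the
recording. The constants suppress single-frame flicker at the default
grid and are all configurable. Breath-cycle duration is the interval
between successive breath-segment onsets (`NA` below two breaths).

## The recording feature vector and partitioning

`aggregate_recording_features()` produces the canonical 23-feature vector:
per-kind means of the nine frame features (18), breath/speech counts and
total durations (4), and mean breath cycle duration (1). Sex, height and
weight extend it to 26. A recording with no detected breath yields `NA`s
that are imputed from training-row medians only.

Min-max normalisation is fitted on training rows only and applied without
clipping; fitting on all rows would leak test information into the scale.
Severity grades use a configurable boundary table (normal > 80;
mild 70–80; moderate 60–<70; moderately-severe 50–<60; severe 35–<50;
very-severe < 35); the binary label is normal ⇔ FEV1% > 80, with 80.0
abnormal, and the grade table keeps 80 as an edge so the two labelings
always agree on "normal".

Balanced partitioning bins FEV1% into half-open 5-point bins ((50, 55],
…, (120, 125]) and splits each bin 70:30 with ties toward training and
singletons in training, so the train and test FEV1% histograms differ by
at most one sample per bin. The split unit is the *recording*, not the
subject: with repeated measurements per subject this leaks subject
identity across splits, but it is the design under which the reference
performance figures for this kind of pipeline are quoted, and subject
identity is excluded from the features. A stricter grouped split can be
composed from `make_partition()` on subject-level FEV1% summaries.

## Models and evaluation

"Linear" means ordinary least squares for regression, logistic regression
for the binary task and multinomial logistic regression for the
multi-class task (`linear_multiclass = "lsq"` offers a literal
least-squares-on-class-codes variant for comparison). Defaults are pinned
rather than inherited — 500 trees; SVM cost 1, RBF γ = 1/p, ε-regression —
so "default hyperparameters" mean the same thing across library versions.
The SVM sees already-normalised features (`scale = FALSE`). Binary ROC
scores are probabilities for linear/forest models and raw decision values
for the SVM (rank information only, no calibration).

`run_task_suite()` crosses 3 tasks × 3 algorithms × {with, without}
biological covariates = 18 reports sharing one partition and seed, each
with seeded 10-fold CV on the training split and held-out test metrics:
RMSE/MAE; accuracy, per-class precision/recall/F1 (macro and weighted),
sensitivity (recall of abnormal) and specificity; ROC points with AUC
computed both as trapezoidal area and by pair counting (the two agree to
1e-9 and are asserted to). `compare_feature_sets()` refits the regression
on breath-only, speech-only and combined features under one partition.

## Problem sizes used by the tests

Unit tests run on an 8 kHz, 8 s cohort of 44 recordings. The end-to-end
property checks use: 50 full-rate 30 s recordings for segmentation
recovery (frame accuracy ≥ 0.95, per-kind segment recall ≥ 0.9); the full
323-recording manifest for partition balance; and 20 seeded repetitions
of 36-recording cohorts for signal recovery (median best regression RMSE
≤ 6 FEV1% points and median binary AUC ≥ 0.9 at `noise_sd = 2`), plus
18-recording cohorts with `cycle_slope = 0` — signal in breath acoustics
only — to check that combined features do not lose to speech-only
features. These sizes are the package's choice of a fast, stable test
design; `scripts/acceptance.R` runs the full 26-subject, 323-recording
cohort.

## Known limitations

* Synthetic speech is a harmonic proxy; features that depend on phonetic
  variety (e.g. ZCR contrasts between fricatives and vowels) are milder
  here than in real speech.
* Threshold calibration assumes exemplar labels; with none, rules must be
  supplied.
* With ~36–100 recordings, held-out test splits are small and per-seed
  metrics are noisy; medians over seeds are the stable summary.
* The severity task inherits heavy class imbalance from the cohort shape
  (most samples normal); per-class metrics on rare grades are fragile.
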