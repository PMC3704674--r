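---
title: "Simulating and classifying GC-sensor urine headspace chromatograms"
author: "gcvoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and classifying GC-sensor urine headspace chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcvoc)
```

## The problem

A gas chromatograph coupled to a heated metal-oxide sensor turns the volatile
organic compounds (VOCs) in the headspace above a urine sample into a
*resistance-time chromatogram*: sensor resistance sampled every 0.5 s for
42 min, i.e. 5040 points per sample. In a pilot diagnostic study of this
design, chromatograms from patients with transitional cell carcinoma of the
bladder and from symptomatic non-cancer controls were separated by two
independent statistical routes: a parsimonious forward-stepwise linear
discriminant over individual time points, and a PLS-DA classifier over the
whole profile. `gcvoc` implements that complete workflow — standardization,
peak diagnostics, both classifiers, leave-one-out cross-validation (LOO-CV),
and an evaluation harness — together with a seeded generator of synthetic
cohorts, because the underlying patient dataset is not publicly deposited.
Every stage of the pipeline can therefore be exercised, tested and
benchmarked without external data.

## The generator: what it emulates

`simulate_cohort()` draws a cohort of `n_cancer + n_control` chromatograms
(24 + 74 by default) under an explicit instrument/disease model
(`sim_config()`):

* **Peaks** are Gaussian in the time index. Peak shape is not parameterized
  by the instrument description; a Gaussian is the minimal unimodal model
  consistent with the plotted chromatograms and the stated widths (average
  full width circa 100 half-seconds, up to circa 200 at high retention
  times). The default shared-peak library spans the elution range with
  `width_sd` growing from ~20 to ~50 half-seconds.
* **The cancer-marker peak** sits at index 3204 and is assigned *without
  replacement* to exactly `round(prevalence * n)` samples per group —
  20 of 24 cancers and 0 controls by default — so the generator contract is
  testable deterministically rather than Bernoulli-approximately.
* **Retention-time jitter** is one multiplicative factor per run, drawn
  uniformly on `[1 - j, 1 + j]` with `j = 0.01`, applied to every peak
  center in that run. A single per-run factor matches the observation that
  tracked peaks co-fluctuate day to day by circa ±1%.
* **Baseline drift** is a per-run random level (sd 2 raw units around a
  start level of 20) plus a gentle within-run linear slope (sd `3e-4` units
  per grid step); no functional form is prescribed by the source
  description beyond "drift", so the simplest level-plus-trend model is
  used. Additive white noise (sd 0.15) completes the trace.
* **Sign convention**: the physical sensor responds with a resistance
  *drop*; traces are emitted already inverted, so peaks are maxima on a
  positive baseline, matching how such chromatograms are plotted.
* **Calibration runs** (`simulate_calibration_series()`) emulate the daily
  ethanol standard: a true retention time drawn around 329.2 half-seconds
  (SD 3.97) is *recovered by peak detection* on a rendered noisy trace, and
  the daily sensitivity (mean 98.5%, SD 10.6, truncated to the physical
  range of a resistance-drop sensor) is expressed as a baseline/exposed
  resistance pair so that `sensor_sensitivity(r0, rg) = 100 (r0 - rg) / r0`
  reproduces it.

### Calibrated effect sizes

The study reports *where* the groups differ (nine discriminating time
points, one dominant marker region) and *how well* the classifiers perform,
but not the amplitudes of the underlying differences. Those amplitudes are
therefore **calibration constants of the default configuration**, not
physical measurements: the eight secondary amplitude shifts
(`default_secondary_effects()`: 1.5–2.5 raw units at time points 117, 153,
174, 201, 359, 1073, 1162, 1362) and the marker amplitude (6 raw units,
CV 0.2) were chosen once so that both end-to-end pipelines reach at least
the study's cross-validated rates (95.8% sensitivity and 93.2% / 94.6%
specificity) in the median over 20 seeded cohorts, with enough margin that
the outcome is stable across seed windows. They live in `sim_config()`, not
in code, and can be varied freely.

### What the generator does *not* emulate

* Controls never carry marker-region peaks at the default
  `prevalence_control = 0`, whereas in the real data such peaks were only
  "predominantly" absent. Because the marker feature then gives every
  control a wide margin, simulated specificities sit at ~100% rather than
  the reported 93–96%: the default disease model has no mechanism for the
  handful of control-side errors in the published tables. Raising
  `prevalence_control` (e.g. to 4/74) restores that error mode if wanted.
* No adsorption kinetics, temperature-ramp chemistry, column aging, or
  sample storage/freezing effects; no non-Gaussian peak tailing; no
  heteroscedastic detector noise. Passing tests demonstrate correctness of
  the statistical machinery under the declared model, not instrument-level
  realism.

## Standardization

Each profile is rescaled to mean 0 and standard deviation 1
(`standardize()`). This removes the run-to-run baseline level and detector
gain (any positive affine transform of a trace standardizes identically)
while preserving relative minima and maxima within the profile. The sample
(n − 1) standard deviation is used; with 5040 points the difference from the
population convention is ~0.01%, but one convention must be fixed for
bit-reproducibility. No baseline subtraction or retention-time alignment is
applied before modelling — the classifiers operate on raw time-point columns
deliberately, mirroring the original analysis, which argued that broad peaks
make ±1% drift immaterial (an argument `jitter_robustness()`
operationalizes).

## Method 1: forward stepwise LDA

`forward_stepwise_select()` greedily builds a time-point subset for a
two-group Fisher discriminant, under the two constraints of the original
analysis: the model may never hold more predictors than the smallest group
(default cap 9, at most 24), and no entering predictor may introduce
multicollinearity. Concretely, at each step the candidate minimizing Wilks'
lambda of the augmented model enters, provided

* its **tolerance** — 1 minus the R² of the candidate regressed (within
  groups) on the already-selected features — is at least `0.001`, and
* its **F-to-enter** exceeds `3.84`.

Both thresholds are the conventional stepwise-discriminant defaults; the
original analysis names the algorithm but not its thresholds. The scan is
incremental: conditional sums of squares come from Schur complements of the
within-group and total scatter matrices, so a full pass over all 5040
candidates costs one `k x p` cross-product per step and the nine-step
selection runs in well under a second. An optional `prescreen` argument
restricts the scan to the strongest single-feature candidates, useful when
the selection itself is repeated inside every cross-validation fold.

`fisher_fit()` then fits the classical two-group discriminant on the
selected columns: direction `S_pooled^{-1} (m1 - m0)`, threshold from the
projected group means plus the log prior odds. Priors default to equal
(0.5/0.5) despite the 24/74 imbalance — the high reported cancer sensitivity
is consistent with non-proportional priors — and proportional priors are
available by argument. Ties exactly at the threshold go to the control
class, a benign convention for a probability-zero event.

### LOO-CV protocols

The original description leaves open whether feature selection was repeated
inside each leave-one-out fold. `lda_loocv()` implements both protocols:

* `fixed_features` (default): time points selected once on the full sample,
  only the discriminant coefficients refit per fold. This mirrors what
  classical stepwise-DA software reports and is the protocol most plausibly
  behind the published table.
* `reselect_per_fold`: the entire stepwise selection re-run on every fold —
  the honest protocol. On null cohorts with zero group effects it stays at
  chance, whereas the fixed protocol shows the well-known selection-bias
  inflation; the test suite asserts both behaviours, which is exactly why
  both protocols are exposed.

## Method 2: PLS-DA

`plsda_fit()` implements PLS1 against the binary class indicator
(control = 0, cancer = 1; decision threshold 0.5 — one of the equivalent
affine conventions, fixed and documented). With a univariate response, each
NIPALS factor extraction is a single closed-form pass: weight vector
proportional to the covariance of the deflated predictors with the centered
indicator (normalized to unit length), scores orthogonal by construction,
predictors deflated by the rank-one score–loading product; the response is
not deflated (redundant for univariate y). Predictors are the per-profile
standardized traces with column centering inside the fit and **no**
additional per-column scaling — the original analysis standardizes within
profiles only. `plsda_loocv_sweep()` reproduces the published factor sweep:
for 1–10 latent factors it reports within-sample and leave-one-out correct
counts and percentages per group, refitting (centering included) on every
n − 1 subset.

## Evaluation harness

`confusion()` builds the 2x2 table with cancer as the positive class and
carries exact percentages (printed to one decimal, matching the published
formatting). `replicate_study()` runs the full pipeline per seed and
summarizes medians; `jitter_robustness()` repeats it across retention-time
jitter levels. "Negligible effect of ±1% jitter" is operationalized as a
median LOO accuracy change of at most 5 percentage points relative to zero
jitter — no numeric tolerance was stated — and gross jitter (50%) must
degrade accuracy, which it does (median accuracy drops by roughly ten
points as the marker region migrates out of its window).

## Numerical choices and degenerate inputs

* Constant traces cannot be standardized (zero variance) and raise a
  degenerate-input error; candidate features with (near-)zero within-group
  variance are excluded from the stepwise scan since they would make the
  pooled covariance singular, and `fisher_fit()` reports a multicollinearity
  error if a singular pooled covariance slips through.
* Wilks' lambda ratios are clamped to [0, 1] against floating-point
  cancellation; the per-step lambda of an entering candidate is always ≤ 1,
  so the cumulative Wilks' lambda is non-increasing along the entry order
  (asserted in the tests).
* PLS extraction stops with an explicit rank-exhaustion error when the
  residual covariance with the indicator vanishes.
* All randomness flows from the single integer `seed` in `sim_config()`;
  identical seeds give bit-identical cohorts, and the generator restores the
  caller's RNG state. Configurations are fingerprinted (32-bit FNV-1a over
  the flattened key-value form) and the fingerprint is embedded in every
  emitted artifact.
* Time-point indices are 1-based (`t = 1..5040`) everywhere, and CSV trace
  columns are zero-padded (`t0001`) so lexical and numeric orders agree.

## Problem sizes used in the shipped checks

The packaged tests exercise the full-size study conditions (98 samples x
5040 points, 20-replicate studies) for the headline reproduction, the
null-leakage guard and the jitter experiment, and a reduced 26-sample x
1200-point configuration for structural and property tests where the grid
size is immaterial. The acceptance script regenerates everything from
scratch at full size.

## Known limitations

* The simulated specificity ceiling discussed above: without control-side
  marker prevalence the control error rate of the published tables cannot
  be reproduced, only exceeded.
* Secondary group effects are amplitude shifts of existing peaks at fixed
  locations; the alternative published 9-point discriminant model (points
  231, 362, 1090, ... spanning the marker region) arises in our cohorts
  only insofar as neighbouring columns of a broad peak carry the same
  information.
* LOO-CV is the only validation scheme implemented, as in the original
  analysis; no ROC/AUC machinery is provided.
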