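---
title: "Methods: HRV phenotyping from the orthostatic stand-up challenge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV phenotyping from the orthostatic stand-up challenge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvpc)
```

## The problem

Diffuse (dcSSc) and limited (lcSSc) cutaneous systemic sclerosis differ in
prognosis and management, but the subtype assignment rests on clinical
expertise. Cardiovascular autonomic function, read out through heart rate
variability (HRV), differs between the subtypes — most visibly in how the
heart responds to standing up. `hrvpc` implements the full analysis chain
needed to exploit this: single-lead ECG to beat-to-beat RR intervals,
RR intervals to a 29-metric HRV profile per 5-minute segment, paired
supine (S1) / standing (S2) profiles plus their stand-up differences
(`_delta`) to a cohort feature table, and from there univariate and
factorial statistics, feature ranking, and a combinatorial benchmark of
classifier families.

Because no patient recordings ship with the package, a synthetic-data
module is a first-class component: it generates cohorts whose group-wise
structure mirrors the clinical phenomenon (direction and rough magnitude),
so every stage of the pipeline is exercised end-to-end by the test suite.

## Signal chain

**QRS detection.** `detect_r_peaks()` implements the Pan–Tompkins chain:
zero-phase 5–15 Hz Butterworth band-pass, derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds with a 200 ms
refractory period. Two details matter numerically. First, each trigger is
refined to the raw-signal argmax within ±50 ms, so RR intervals are not
biased by filter delay. Second, a stronger integrated-signal candidate
arriving inside the refractory window *replaces* the previous trigger
rather than being discarded; without this, a noise bump shortly before a
QRS complex can capture the trigger and suppress the true beat.

**Artifact correction.** A beat is flagged when its interval deviates more
than 30% from the running median of 11 surrounding beats (`dev_threshold`
and `window` are configurable); flagged beats are re-filled by natural
cubic-spline interpolation over beat time and marked `"interpolated"`.
Segments with more than 20% edited beats are rejected — this gate also
drives subject exclusion in `build_cohort()`. The rule is deliberately
deterministic: visual editing cannot be reproduced, a median filter can.

**Resampling and detrending.** Spectral analysis requires uniform
sampling: the tachogram is cubic-spline resampled at 4 Hz and detrended
with a 3rd-order polynomial before the Welch estimate. Time-domain and
nonlinear metrics intentionally use the *corrected beat-to-beat series
without detrending*: beat ordering is the object these metrics quantify,
and detrending the tachogram would alter SD2, DFA and the entropies in
ways that standard HRV software does not.

## Metric definitions and numerical choices

**Time domain.** `mean_RR`, `sd_RR`, `mean_HR`, `sd_HR` (per-beat
instantaneous HR = 60000/RR, sample SDs), `RMSSD`, `NN50` (strict
`> 50 ms`), `pNN50` = 100·NN50/(n−1).

**Frequency domain.** Welch periodogram: Hann window of
min(duration, 256 s), 50% overlap, mean removal per segment. The one-sided
density is rescaled so its trapezoidal integral over (0, fs/2] equals the
input variance exactly; windowing and finite segmentation otherwise bias
the integral by a few percent, and downstream band powers inherit the
normalisation. Bands: VLF 0.003–0.04 Hz (needed for total power and
normalized units, configurable), LF 0.04–0.15 Hz, HF 0.15–0.4 Hz. Band
powers by trapezoidal integration with edge interpolation; `*_nu` divides
by (total − VLF); band peaks are the argmax frequency (a spectral-centroid
mode is available via `peak_mode = "centroid"`).

**Poincaré geometry.** SD1² is half the *uncentered* second moment of the
successive differences, so the classical identity SD1 = RMSSD/√2 holds
exactly on every series (a centered variance breaks it whenever the mean
successive difference is non-zero, i.e. on any trending segment);
SD2² = 2·var_pop(RR) − SD1², clamped at zero. A strictly alternating
series therefore has SD2 = 0 exactly.

**Recurrence quantification.** Embedding dimension 10, lag 1, threshold
r = √m·SD of the series, Euclidean distance, minimum line length 2. The
line of identity is excluded everywhere; diagonal lines are counted on the
upper triangle (the matrix is symmetric, so triangle-based counting equals
full-matrix counting in every ratio). REC is the percentage of recurrent
off-diagonal pairs; DET the percentage of recurrent points lying on
counted lines; ShanEn the natural-log Shannon entropy of the counted
line-length histogram. A Theiler window beyond the line of identity is
available but defaults to 0, matching the all-pairs definition.

**Entropies.** ApEn and SampEn with m = 2, r = 0.2·SD, Chebyshev
distance. ApEn includes self-matches (Φ_m − Φ_{m+1}); SampEn excludes
them, counting pairs over the first N−m templates at both lengths, and
returns NaN with a warning when no pair matches. Both are exactly
invariant to adding a constant (r is tied to the SD).

**DFA.** Profile = cumulative sum of the mean-centered series;
non-overlapping boxes; per-box linear detrending; α1 fit over integer box
sizes 4–16, α2 over 16–64. One property deserves emphasis: at boxes 4–16
the *expected* log–log slope for uncorrelated noise is 0.583, not the
asymptotic 0.5 — a known small-scale property of DFA-1 whose exact value
follows in closed form from the Brownian covariance and the linear-fit hat
matrix. The test suite asserts the estimator against that exact
expectation rather than against the asymptote. We deliberately do not
apply a finite-size correction: the correction that makes white noise read
0.5 shifts integrated noise from 1.50 to ≈1.42, and physiologic series
(α ≈ 1) sit between the two regimes. The uncorrected estimator is also
what the field's standard HRV software computes, which keeps cohort values
comparable.

**Correlation dimension.** Grassberger–Procaccia: the correlation sum
C(r) is the fraction of distinct embedded-point pairs closer than r
(an i<j sum with a 1/(N(N−1)) prefactor, as sometimes printed, yields
exactly half this value — a constant factor invisible to log–log slopes;
the fraction convention makes C → 1 as r → ∞). The dimension is the local
least-squares slope of log C vs log r on a 30-point geometric radius grid
spanning [0.025, 1]·√m·SD, read at the 5 points centred nearest
r = 0.15·SD. A literal r → 0 limit is undefined on finite data, and at
5-minute segment lengths (~390 embedded points, ~57k pairs) C is not
resolvable below ≈2·10⁻⁵, which typically zeroes the nominal window; the
slope window then slides to the smallest radii with at least 5 recurrent
pairs and C < 1 — the closest realizable approach to the small-radius
limit. NaN is returned only when fewer than 3 usable radii exist on the
whole grid. With this estimator a clean limit-cycle RR modulation reads
≈1 and white noise climbs toward the embedding bound, preserving the
ordering the dimension is meant to capture.

## Cohort assembly and statistics

`hrv_vector()` evaluates a fixed 29-metric registry (7 time, 10 frequency,
12 nonlinear) per segment; `build_cohort()` produces one row per subject
with `{metric}_{S1|S2|delta}` columns (87 features) plus the group label,
excluding subjects that fail the quality gates and logging why. Lmin
(constant and equal to the configured minimum line length on physiologic
segments), DIV (= 1/Lmax) and the SD1/SD2 ratio are computed by their
operations but excluded from the registry as degenerate or strictly
redundant.

Group comparisons are normality-gated: Shapiro–Wilk on each group, Welch
t-test when both pass at 0.05, Mann–Whitney otherwise; the chosen test is
part of the result. Contingency tables use Fisher's exact test when any
expected 2×2 cell is ≤ 5, chi-square otherwise. The position × clinical
form analysis is a mixed (split-plot) ANOVA — clinical form is
between-subject, position within-subject — with Bonferroni ×3 across the
three effects per variable; when the cell-means residuals fail normality
the Scheirer–Ray–Hare rank-based factorial is used instead, reporting H
statistics against a chi-square reference. Correlation matrices choose
Pearson vs Spearman per pair by the same normality gate and mask entries
with p ≥ 0.05.

## Feature engineering and benchmark

Features are screened at unadjusted p < 0.1, pruned for collinearity
(greedy pass over pairs with R² > 0.9 in decreasing R² order; the kept
member is chosen by a fixed priority — stand-up deltas over standing over
supine, then registry order, then name — making the pass deterministic and
row-order independent), and min–max scaled. Five selectors each produce a
full ranking: bagged-tree impurity (random forest with mtry = p),
extremely-randomized-tree impurity, univariate F score, univariate mutual
information (equal-width 8-bin discretisation), and recursive elimination
of the smallest absolute logistic-regression coefficient. The
redundancy-weighted score is mean rank + rank SD (the SD weight is
configurable): a feature must rank well *and* consistently. A second,
independent ordering uses the gamma separability index
|μ₁−μ₂|/√(σ₁²+σ₂²). `select_top()` admits the intersection of both top-k
lists automatically and fills remaining slots by a configurable arbiter,
including a manual-override hook for expert choices.

The benchmark evaluates every combination of 1–5 selected features
(31 subsets for 5 features; 341 cells with the 11-algorithm registry)
under a stratified 80/20 split. Class imbalance is handled by SMOTE
(synthetic minority points drawn uniformly on segments toward one of the
k = 5 nearest minority neighbours); the default policy applies SMOTE
strictly inside training folds so no synthetic sample can leak into a
held-out fold — the `before_split` policy reproduces the
balance-then-split order some studies describe, and is provided for
comparability with that known leakage risk. Metrics: Brier-style MSE,
log loss, sensitivity, specificity, precision, accuracy, rank-based
(trapezoidal) ROC AUC, and F1 as the harmonic mean of precision and
sensitivity. The positive class is dcSSc. Repeated stratified k-fold CV
(5 × 10 by default where enabled) yields per-metric dispersion; the
reported per-combination winner is chosen by validation F1. Both
gradient-boosting registry entries are realized with xgboost under
distinct hyperparameter profiles (classic slow-learning depth-3 GBM vs
default-style depth-6); the stacked ensemble combines logistic regression,
random forest and GBM through a logistic meta-learner fit on out-of-fold
predictions.

## The synthetic cohort generator

`ipfm_generate()` uses the integral pulse frequency modulation model: a
beat fires whenever the integral of m(t)/T̄ crosses an integer, with
m(t) = 1 + a_LF·sin(2πf_LF t + φ₁) + a_HF·sin(2πf_HF t + φ₂) +
noise_sd·z_β(t). This forward model is standard in HRV methodology because
the knobs map directly onto the measured quantities: a_LF and a_HF set the
LF/HF band powers, target HR sets mean_RR/mean_HR, and the exponent β of
the band-limited 1/f^β noise moves the fractal and complexity metrics
(DFA α, correlation dimension) smoothly — higher β means smoother,
lower-dimensional dynamics.

The default two-group preset encodes the study conditions rather than
free parameters: heart rates 74/88 bpm (dcSSc S1/S2) vs 68/77 bpm
(lcSSc), amplitude and noise levels chosen so the fractional RR
variability reproduces the reported sd_RR/sd_HR magnitudes, and a
noise-exponent contrast (dcSSc stiffening to β = 1.5 on standing, lcSSc
loosening to β = 0.9) that produces the opposite-signed stand-up responses
of SD2, sd_HR and CorDim between groups. Group sizes default to 16/42.
Per-subject parameters are log-normal jitters around the cell means with
the subject-level factor *shared between positions*, so the paired design
is genuine. The generator emulates stationary 5-minute segments with
autonomic-like modulation; it does not emulate respiration–volume
coupling, ectopy (injected separately by `inject_ectopic()`), transient
stand-up dynamics, or measurement artifacts — so passing tests demonstrate
pipeline correctness and direction recovery, not clinical performance on
real recordings.

## Problem sizes used by the test suite

The suite verifies oracle equivalence (RQA, entropies, correlation sums
against brute-force O(N²) enumerations) on 50 series of 20–40 beats;
analytic limits on 10 000-point noise series; and direction recovery on
twenty 58-subject synthetic cohorts with the benchmark run on ten of them
under validation-only scoring. These sizes keep a full run at desk scale
while leaving every stage exercised end-to-end; all stochastic steps are
seeded.

## Known limitations

* Metric values are Kubios-convention-like but not bit-compatible with any
  specific software; conventions are documented per operation and
  configurable where the field varies (REC denominator, Theiler window,
  VLF band, peak mode, CorDim window).
* The correlation-dimension estimator reads a local slope, not an
  asymptotic limit; its absolute values on short noisy segments are
  estimator-dependent and should be compared within, not across,
  processing pipelines.
* DFA α1 over boxes 4–16 carries the intrinsic small-scale bias discussed
  above; comparisons are valid between groups processed identically.
* The benchmark reports honest held-out metrics at n = 58 scale; with
  ~12 validation subjects the metric granularity is coarse, which is why
  the suite tests seed-averaged orderings rather than point values.
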