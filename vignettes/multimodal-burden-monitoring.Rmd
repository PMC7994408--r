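---
title: "Methods: joint ctDNA and FTV monitoring during neoadjuvant chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint ctDNA and FTV monitoring during neoadjuvant chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nactrack)
```

# Scope and data model

`nactrack` analyses cohorts in which each patient contributes up to four
serial measurements of two tumor-burden modalities — functional tumor
volume (FTV, cm³) from dynamic contrast-enhanced (DCE) MRI, and plasma
ctDNA concentration (mean tumor molecules per mL, MTM/mL) from a
tumor-informed assay — at timepoints T0 (pretreatment), T1 (three weeks
into taxane-based treatment), T2 (between regimens) and T3 (after
neoadjuvant chemotherapy, before surgery), plus per-patient covariates
(subtype, clinical stage, MammaPrint risk category) and outcomes
(pathologic complete response, pCR; distant recurrence-free survival,
DRFS). The canonical container is a long-format table, one row per
patient-timepoint, with per-patient fields repeated (`read_cohort`,
`write_cohort`, `validate_cohort`). Validation flags — never repairs —
violations such as a "positive" ctDNA status with zero concentration.

# Functional tumor volume

Per voxel, percent enhancement is `PE = 100 (S_post − S_pre) / S_pre`,
with `S_pre` the pre-contrast frame (always the first frame). FTV is the
number of voxels inside a delineated ROI box with `PE ≥ threshold`, times
the voxel volume. Defaults and conventions:

* `threshold_pct = 70` and `eval_time_s = 150` (about two and a half
  minutes post-contrast). Acquisition grids vary, so the *nearest*
  post-contrast frame to `eval_time_s` is used; a tie goes to the earlier
  frame.
* The threshold comparison is inclusive: a voxel at exactly 70 % counts.
* Voxels with `S_pre = 0` cannot be evaluated; they are excluded and
  counted (`n_non_evaluable`) rather than treated as infinitely enhancing.
  If every ROI voxel is non-evaluable the FTV is 0 with a warning.
* Arrays are ordered (time, z, y, x); ROI bounds are 1-based inclusive
  ranges, the natural R convention.

Out of scope by design: automated lesion segmentation (the ROI box is an
input), pharmacokinetic modelling, and signal-enhancement-ratio criteria
beyond the single PE threshold.

# Cross-sectional association

At each timepoint, patients with both measurements form the analysis set
(listwise per timepoint; dropped counts are reported). Spearman's ρ is
computed as the Pearson correlation of midranks, with a two-sided p from
the t approximation on n − 2 degrees of freedom. ctDNA concentration
enters *as reported*, i.e. zeros for ctDNA-negative samples: the rank
statistic then treats all negatives as one tied block at the floor, which
is how scatter plots with negatives at the detection limit behave. The
rank-sum comparison of FTV by ctDNA status uses exact enumeration of all
group assignments when both groups have ≤ 8 observations (valid under
ties) and a tie-corrected, continuity-corrected normal approximation
otherwise.

# Trajectory concordance

The question is whether a patient's ctDNA and FTV series co-move beyond
the population-wide decline during treatment. Restricted to patients
ctDNA-positive at baseline:

1. Per patient, Pearson `r_i` between the FTV and MTM series over
   timepoints where *both* are present. Eligibility requires
   `min_timepoints = 3` complete pairs (a 2-point correlation is always
   ±1 and would distort the mean) and nonzero variance in both series.
   Correlations of exactly ±1 are clipped to ±(1 − 10⁻⁷) before the
   Fisher transform; clips are counted.
2. The observed statistic is `z̄ = mean(atanh r_i)` — the Fisher transform
   normalizes the r distribution so the mean is well-behaved.
3. The null reference re-pairs patient `i`'s FTV series with a uniformly
   random permutation's ctDNA series (fixed points allowed — the scheme is
   plain label permutation, not a forced derangement), recomputing `z̄`
   each time; pairings with fewer than `min_timepoints` overlapping
   observations are skipped within an iteration. `B = 1000` by default,
   or exhaustive enumeration of all `n!` pairings for `n ≤ 8`.

The empirical two-sided p is add-one corrected:
`p = (1 + #{b : |z̄_b − c| ≥ |z̄_obs − c|}) / (B + 1)`, with `c` the
**mean** of the permutation distribution. Two points deserve emphasis.
First, the null center is far from zero whenever all patients improve:
randomly re-paired declining series still correlate, so the test isolates
patient-specific concordance. Second, the center functional was a
genuinely open design choice; the median was considered and rejected
because on small cohorts the permutation distribution is discrete and its
median can be ambiguous (two central atoms splitting the mass), in which
case exhaustive and Monte Carlo estimates of the same p diverge by an
atom gap. The mean is a continuous functional of the permutation
distribution, so the two modes converge; `center = "median"` remains
available.

A seed is mandatory — the full result object (including the permutation
means, for audit) is bit-reproducible.

# pCR prediction

FTV-based predictors are transparent two-feature logistic models per
timepoint: `log(FTV_T0 + 1)` and the relative change
`(FTV_Tk − FTV_T0) / max(FTV_T0, 0.01 cm³)`. These stand in for
externally trained, subtype-specific FTV models (which depend on data not
distributed with any cohort table); the train/evaluate split discipline
is preserved, which makes *absolute* AUC levels cohort-specific — only
the comparison between FTV-only and ctDNA-augmented models is meaningful
here. Fitting is unpenalized maximum likelihood; complete separation is
detected (non-convergence or diverging coefficients) and reported rather
than silently regularized.

ctDNA augmentation candidates are baseline concentration (entering as
`log(MTM_T0)`; the analysis set is restricted to baseline ctDNA-positive
patients, so `MTM_T0 > 0`) and its percent change to the timepoint on the
MTM scale — the scale choice is exposed rather than hidden, since percent
change of a log-scale quantity is a different covariate. Model selection
evaluates the four candidate sets {∅, baseline, change, both} by
cross-validated AUC and keeps the argmax, breaking ties toward fewer
features.

Cross-validation is stratified by pCR (within-class shuffling, then
round-robin dealing across a running fold counter, so `k = n` degenerates
exactly to leave-one-out), refits per fold, and scores **pooled**
out-of-fold predictions with one AUC — more stable than averaging
per-fold AUCs at n ≈ 50 and required anyway for a single dichotomization
threshold. The AUC is the Mann–Whitney estimator (ties count ½), which
equals the trapezoidal area under the empirical ROC. Dichotomization
picks the ROC point minimizing the Euclidean distance to perfect
classification, `√((1 − sens)² + (1 − spec)²)`, ties to higher
sensitivity; PPV, NPV and accuracy follow, with empty denominators
reported as `NA` per metric.

# Survival analysis

DRFS is modelled by Cox partial likelihood with Efron tie handling (the
default of the standard survival software, making log-likelihoods and AICs
comparable to common practice). Covariates are anchored at T3 — residual
burden after treatment — with earlier timepoints influencing DRFS only
through T3: continuous FTV (per cm³), ctDNA status (0/1), optionally
their product interaction, pCR, and subtype dummy-coded with HR+HER2− as
the reference level (configurable by releveling the factor). Records with
missing covariates are dropped listwise and counted. Wald 95 % CIs are
normal approximations on the log-hazard scale. Diagnostics use scaled
Schoenfeld residuals with the Kaplan–Meier time transform by default
(`rank` and `identity` available). Model comparison fits every candidate
on the common complete-case subset (AICs are otherwise incomparable),
reports `AIC = −2ℓ + 2k`, and adds a likelihood-ratio p against the
largest nested parent in the candidate list.

# The synthetic-cohort generator

The generator exists so every stage is testable without patient data. Per
patient *i* (all draws from a per-patient substream of the global seed, so
extending a cohort never perturbs existing patients):

* subtype ~ categorical(29, 19, 36)/84; age ~ N(49.3, 11²) clipped to
  [25, 73]; treatment arm, nodal stage, grade (⅓ missing) and MammaPrint
  category drawn at the frequencies of a high-risk NAC trial cohort;
  clinical T stage is tied to baseline FTV so larger tumors are T3/T4.
* latent baseline log burden `b_i ~ N(3, 1)` (median FTV ≈ 20 cm³) and
  response factor `r_i ~ N(0.8, 0.5)`;
  `log FTV_ik = b_i − r_i k + ε, ε ~ N(0, 0.3²)` for `k = 0..3`.
* `log MTM_ik = a₀ + u_i + log FTV_ik + e, u_i ~ N(0, 1), e ~ N(0, σ_e²)`.
  Concentrations below the detection limit (0.1 MTM/mL) are reported as 0
  with negative status — zero inflation comes from thresholding a
  continuous latent, so status and concentration can never disagree. The
  intercept `a₀` is solved so baseline positivity is 53/84, and `σ_e` so
  the *full-sample* zero-inflated Spearman correlation between FTV and
  MTM equals `rho_target` (default 0.45): the population grade
  correlation of a bivariate normal with one variable floored is computed
  by two one-dimensional Gaussian integrals and inverted by root-finding.
  The correlation among detectable samples only is necessarily lower
  (≈ 0.35 at the defaults) — one latent correlation cannot pin both
  quantities, and the full-sample version is what burden-vs-burden scatter
  plots report.
* pCR ~ Bernoulli(logistic(c₀ + 2 r_i)), with c₀ solved by Gaussian
  integration so the marginal rate is `pcr_rate_target` (default 23/84).
* DRFS time is exponential with hazard
  `h₀ exp(log(11.5)·ctDNA⁺_T3 + log(1.03)·FTV_T3)`, `h₀ = 0.015/yr`,
  censored uniformly on (0, 6.3] years — roughly one distant
  recurrence/death per eight patients, matching the scale of a pilot
  cohort with few events.
* T1–T3 rows are dropped completely at random at `missing_rate = 0.15`
  (the missingness mechanism of real cohorts is unknown; MCAR is the
  neutral choice); T0 is never missing.

What the generator does **not** emulate: assay-specific detection noise
near the limit, informative missingness (e.g. sicker patients skipping
MRI), correlation between response and subtype, non-exponential baseline
hazards, and MR physics in the DCE phantoms (no coil profiles or motion).
Passing tests on synthetic data therefore demonstrate the statistical
machinery is correct under the stated model, not that effect sizes
transfer to any real cohort.

The DCE phantom places a spherical (or exact-voxel-count) lesion on a
constant background, applies a per-frame percent-enhancement curve plus
optional Gaussian noise, and records the noiseless above-threshold voxel
count as ground truth, making FTV recovery exactly checkable.

# Numerical choices and degenerate inputs

* Logistic fits: IRLS to tolerance 10⁻¹⁰; Cox fits: Newton iterations with
  the standard survival convergence tolerance; rank-deficient designs are
  rejected naming the collinear columns; monotone likelihood (unbounded
  coefficient) is reported.
* Zero rank variance makes Spearman's ρ undefined — signalled with a
  `degenerate` flag, not returned as 0.
* Timepoints with < 3 complete pairs, single-status cohorts, single-class
  training sets and event-free survival data all produce explicit reason
  codes or errors, never silent numbers.
* Exact rank-sum enumeration is limited to groups of ≤ 8 (C(16, 8) =
  12870 assignments); exhaustive permutation mode to 8 eligible patients
  (8! = 40320 pairings).

# Problem sizes in the test suite

Simulation-backed tests use 2000 patients for correlation and Cox/logistic
parameter recovery (3-SE bands), 5000 for the pCR-rate binomial check,
2000 replicates for the rank-sum type-I calibration, 200 null cohorts ×
199 permutations for the concordance type-I calibration, 400 replicates
for Schoenfeld calibration and the noise-covariate AIC distribution, and
50 seeds for cross-validation nulls and model-selection behaviour. These
sizes put Monte Carlo error comfortably inside each test's assertion band
while keeping the default suite in the low minutes on one CPU.

# Known limitations

* The FTV-based pCR predictor is deliberately simple; its absolute AUC is
  not comparable to externally trained subtype-specific models.
* The concordance p-value depends on stated conventions (centering
  functional, minimum timepoints, clipping); all are exposed as arguments
  and recorded in the result object, but cross-study comparison of p
  requires matching them.
* With ~10 events, hazard-ratio estimates at cohort scale are wide;
  the generator-target recovery checks run at n = 2000 for that reason.
* Percentages in cohort summaries are integer-rounded and may not sum to
  exactly 100.
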