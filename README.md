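# nactrack

Multimodal tumor-burden monitoring during neoadjuvant chemotherapy (NAC)
for early breast cancer: joint analysis of serial circulating tumor DNA
(ctDNA) and MRI functional tumor volume (FTV).

## The problem

During NAC, two very different measurements track how a breast tumor
responds: **FTV**, the volume of tissue enhancing on dynamic
contrast-enhanced MRI (a macroscopic, imaging-based burden measure), and
**ctDNA concentration** in plasma (mean tumor molecules per mL, MTM/mL — a
molecular burden measure from a tumor-informed liquid-biopsy assay, with a
sample called ctDNA-positive when enough tracked variants are detected).
Both are collected at four serial timepoints — T0 (pretreatment), T1
(early taxane), T2 (inter-regimen), T3 (post-NAC, pre-surgery) — alongside
the trial endpoints: pathologic complete response (pCR) at surgery and
distant recurrence-free survival (DRFS).

`nactrack` implements the full analysis pipeline for such cohorts, for
biostatisticians and imaging scientists working on treatment-response
monitoring:

1. **FTV computation** (`compute_ftv`): percent enhancement per voxel,
   `PE = 100 (S_post − S_pre)/S_pre`, evaluated at the post-contrast frame
   nearest ~150 s; FTV is the summed volume of ROI voxels with
   `PE ≥ 70 %`.
2. **Cross-sectional association** (`association_by_timepoint`): Spearman's
   ρ between FTV and MTM/mL at each timepoint, and a Wilcoxon/Mann–Whitney
   rank-sum comparison of FTV by ctDNA status (exact enumeration for small
   groups, tie-corrected normal approximation otherwise).
3. **Trajectory concordance** (`permutation_test`): per patient
   (ctDNA-positive at baseline), the Pearson correlation `r_i` between the
   serial FTV and MTM series; the statistic is the mean Fisher
   z-transform, `z̄ = mean(atanh r_i)`. The null reference randomly
   re-pairs patients' ctDNA series with other patients' FTV series (Monte
   Carlo, B permutations, or exhaustive `n!` enumeration), giving an
   empirical two-sided p centered on the permutation distribution.
4. **pCR prediction** (`cv_auc`, `select_combined_model`,
   `dichotomize_top_left`): logistic FTV predictors per timepoint,
   optionally augmented with baseline ctDNA and its percent change;
   pCR-stratified 10-fold cross-validation scored by pooled out-of-fold
   AUC (Mann–Whitney estimator); ROC dichotomization by distance to the
   top-left corner; PPV/NPV/accuracy.
5. **Recurrence risk** (`fit_cox`, `ph_test`, `compare_models_aic`): Cox
   proportional-hazards models of DRFS on T3 FTV and ctDNA status
   (univariable, bivariable, interaction, multivariable with pCR and
   subtype), Efron ties, Wald CIs, scaled-Schoenfeld proportional-hazards
   diagnostics, and AIC model comparison (`AIC = −2ℓ + 2k`).
6. **Synthetic cohorts** (`sim_config`, `simulate_cohort`,
   `simulate_dce_phantom`): a documented generative model reproducing the
   statistical structure the analyses assume — declining latent burden,
   zero-inflated log-normal ctDNA calibrated to a target rank correlation,
   a target pCR rate, and an 11.5-fold DRFS hazard for T3
   ctDNA-positivity — plus 4D DCE phantoms with exact ground-truth FTV.

## Worked example

```r
library(nactrack)

sc <- simulate_cohort(sim_config(seed = 1))   # 84-patient synthetic cohort
association_by_timepoint(sc$cohort)[, c("timepoint", "n_pairs", "rho", "rho_p")]
#>   timepoint n_pairs   rho    rho_p
#> 1        T0      84 0.468 7.11e-06
#> 2        T1      72 0.498 8.72e-06
#> 3        T2      72 0.487 1.45e-05
#> 4        T3      78 0.537 4.06e-07
```

ctDNA concentration and FTV are correlated at every timepoint (ρ ≈ 0.47–0.54
here; the generator's target is 0.45). Trajectory concordance:

```r
permutation_test(patient_timecourses(sc$cohort), B = 1000, seed = 2)
#> Trajectory-concordance permutation test (mean Fisher z)
#>   observed mean z = 1.4736 over 46 baseline ctDNA-positive patients
#>   Monte Carlo: 1000 pairings, empirical two-sided p = 0.2168
```

The observed mean z is large, but so is the permutation null's center:
every patient's burden declines during treatment, so even randomly
re-paired series correlate — the p-value isolates the *patient-specific*
co-movement beyond that shared decline. Survival:

```r
fit_cox(sc$cohort, c("ftv_t3", "ctdna_t3"))
#> Cox PH fit (Efron ties): n = 78, events = 13 (6 dropped, incomplete covariates)
#>      term   coef    hr ci95_lo ci95_hi     se   wald_p
#>    ftv_t3 0.0193  1.02    1.00    1.04 0.0091 3.38e-02
#>  ctdna_t3 3.4100 30.40    6.06  153.00 0.8230 3.35e-05
```

Residual ctDNA after NAC carries a large hazard for distant recurrence
(the generator's true hazard ratio is 11.5; at 13 events the estimate is
noisy but strongly positive), while FTV contributes ~2 % hazard per cm³.

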