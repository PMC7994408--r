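Package: nactrack
Title: Multimodal Tumor-Burden Monitoring During Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of serial circulating tumor DNA (ctDNA) and
    dynamic contrast-enhanced MRI functional tumor volume (FTV) in the
    neoadjuvant breast-cancer setting. Provides functional tumor volume
    computation by percent-enhancement thresholding of 4D DCE series,
    cross-sectional rank-based association between ctDNA concentration and
    FTV, a Monte Carlo permutation test of per-patient trajectory
    concordance based on mean Fisher z-transformed Pearson correlations,
    cross-validated AUC evaluation of ctDNA-augmented logistic predictors
    of pathologic complete response with ROC top-left dichotomization, and
    Cox proportional-hazards modeling of distant recurrence-free survival
    with interaction tests, Schoenfeld diagnostics and AIC model
    comparison. A synthetic-cohort generator reproduces the statistical
    structure these analyses assume, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
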