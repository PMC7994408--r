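test_that("logistic predictor recovers known coefficients and detects nulls", {
  co <- make_pcr_cohort(5000, seed = 2)
  fit <- fit_ftv_predictor(co, "T1")
  sm <- summary(fit$glm_fit)$coefficients
  expect_lt(abs(sm["log_ftv_t0", "Estimate"] - (-0.8)),
            3 * sm["log_ftv_t0", "Std. Error"])
  expect_lt(abs(sm["ftv_relchange", "Estimate"] - (-2)),
            3 * sm["ftv_relchange", "Std. Error"])

  null_co <- make_pcr_cohort(2000, seed = 3, null_labels = TRUE)
  nfit <- fit_ftv_predictor(null_co, "T1")
  nsm <- summary(nfit$glm_fit)$coefficients
  expect_lt(abs(nsm["log_ftv_t0", "Estimate"]),
            3 * nsm["log_ftv_t0", "Std. Error"])
  expect_lt(abs(nsm["ftv_relchange", "Estimate"]),
            3 * nsm["ftv_relchange", "Std. Error"])
})

test_that("duplicating the training set leaves the fit unchanged", {
  co <- make_pcr_cohort(150, seed = 4)
  dup <- co
  dup$patient_id <- paste0(dup$patient_id, "d")
  both <- rbind(co, dup)
  f1 <- fit_ftv_predictor(co, "T1")
  f2 <- fit_ftv_predictor(both, "T1")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("degenerate training sets are refused", {
  co <- make_pcr_cohort(30, seed = 5)
  co$pcr <- 1
  expect_error(fit_ftv_predictor(co, "T1"), "single pCR class")
  expect_error(fit_ftv_predictor(make_pcr_cohort(10, seed = 6), "T1"), ">= 20")
})

test_that("AUC equals brute-force pair counting and handles ties", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)

  scores <- c(0.1, 0.4, 0.4, 0.6, 0.7, 0.9)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(auc(scores, labels), oracle_auc(scores, labels))

  set.seed(17)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.1), 15, replace = TRUE)
    l <- rbinom(15, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auc(s, l), oracle_auc(s, l))
    # invariance under strictly increasing transform
    expect_equal(auc(qlogis(pmin(pmax(s, 0.01), 0.99)), l), auc(s, l))
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(23)
  s <- rnorm(60); l <- rbinom(60, 1, plogis(s))
  expect_equal(auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("cross-validated AUC is deterministic given the seed and near 0.5 under the null", {
  co <- make_pcr_cohort(500, seed = 7, null_labels = TRUE)
  a <- cv_auc(co, "T1", k = 10, seed = 42)
  b <- cv_auc(co, "T1", k = 10, seed = 42)
  expect_identical(a, b)
  expect_true(all(table(a$folds) >= 45))

  null_aucs <- vapply(1:50, function(i)
    cv_auc(make_pcr_cohort(500, seed = 100 + i, null_labels = TRUE),
           "T1", k = 10, seed = i)$auc, numeric(1))
  expect_gte(mean(null_aucs), 0.46)
  expect_lte(mean(null_aucs), 0.54)
})

test_that("leave-one-out cv_auc equals a brute-force reimplementation", {
  co <- make_pcr_cohort(24, seed = 8)
  n <- 24
  res <- cv_auc(co, "T1", k = n, seed = 1)
  # brute force: refit dropping each patient once
  t0 <- co[co$timepoint == "T0", ]; t1 <- co[co$timepoint == "T1", ]
  df <- data.frame(pcr = t0$pcr,
                   lf0 = log(t0$ftv_cm3 + 1),
                   rc = (t1$ftv_cm3 - t0$ftv_cm3) / pmax(t0$ftv_cm3, 0.01))
  oof <- vapply(seq_len(n), function(i) {
    g <- suppressWarnings(glm(pcr ~ lf0 + rc, data = df[-i, ],
                              family = binomial(),
                              control = list(epsilon = 1e-10, maxit = 100)))
    predict(g, newdata = df[i, , drop = FALSE], type = "response")
  }, numeric(1))
  expect_equal(sort(unname(res$oof_scores)), sort(oof), tolerance = 1e-6)
  expect_equal(res$auc, auc(oof, df$pcr), tolerance = 1e-8)
})

test_that("model selection favours ctDNA features only when informative", {
  # under the null the FTV-only model wins a clear plurality: far above the
  # 25% rate a blind pick among the four candidates would give
  picks_null <- vapply(1:50, function(i) {
    co <- make_pcr_cohort(400, seed = 200 + i)
    length(select_combined_model(co, "T1", k = 5, seed = i)$best_features) == 0
  }, logical(1))
  expect_gte(mean(picks_null), 0.4)

  picks_inf <- vapply(1:20, function(i) {
    co <- make_pcr_cohort(400, seed = 300 + i, informative_ctdna = TRUE)
    length(select_combined_model(co, "T1", k = 5, seed = i)$best_features) > 0
  }, logical(1))
  expect_gte(mean(picks_inf), 0.9)

  tab <- select_combined_model(make_pcr_cohort(200, seed = 9), "T1",
                               seed = 1)$auc_table
  expect_identical(nrow(tab), 4L)
})

test_that("ROC curve is monotone and its trapezoidal area equals the AUC", {
  set.seed(29)
  s <- round(rnorm(80), 1); l <- rbinom(80, 1, plogis(2 * s))
  roc <- roc_curve(s, l)
  expect_true(all(diff(roc$sensitivity) >= 0))       # thresholds decreasing
  expect_true(all(diff(roc$specificity) <= 0))
  expect_equal(oracle_trapezoid_auc(roc), roc$auc, tolerance = 1e-10)
})

test_that("top-left dichotomization picks the hand-computed optimum", {
  toy <- structure(list(thresholds = c(0.7, 0.5, 0.3),
                        sensitivity = c(0.5, 0.7, 0.9),
                        specificity = c(0.95, 0.8, 0.6),
                        auc = NA_real_),
                   class = "roc_curve")
  pick <- dichotomize_top_left(toy)
  expect_equal(pick$sensitivity, 0.7)
  expect_equal(pick$specificity, 0.8)
  expect_equal(pick$cut, 0.5)
  expect_equal(pick$distance, sqrt(0.3^2 + 0.2^2))

  perfect <- structure(list(thresholds = c(0.9, 0.5, 0.1),
                            sensitivity = c(0.4, 1, 1),
                            specificity = c(1, 1, 0),
                            auc = NA_real_),
                       class = "roc_curve")
  expect_equal(dichotomize_top_left(perfect)$distance, 0)

  # never selects a strictly dominated point
  set.seed(37)
  for (i in 1:10) {
    s <- rnorm(40); l <- rbinom(40, 1, plogis(s))
    if (length(unique(l)) < 2) next
    roc <- roc_curve(s, l)
    pick <- dichotomize_top_left(roc)
    dominated <- any(roc$sensitivity > pick$sensitivity &
                       roc$specificity > pick$specificity)
    expect_false(dominated)
  }
})

test_that("classifier metrics match hand arithmetic and flag empty denominators", {
  perfect <- classifier_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(unlist(perfect[c("ppv", "npv", "accuracy")]),
               c(ppv = 1, npv = 1, accuracy = 1))

  all_high <- classifier_metrics(rep(TRUE, 10), rep(c(TRUE, FALSE, FALSE,
                                                      FALSE, FALSE), 2))
  expect_equal(all_high$ppv, 0.2)
  expect_true(is.na(all_high$npv))
  expect_equal(all_high$accuracy, 0.2)

  pred <- c(rep(TRUE, 8), rep(FALSE, 12))
  truth <- c(rep(TRUE, 5), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 10))
  m <- classifier_metrics(pred, truth)
  expect_equal(m$ppv, 5 / 8)
  expect_equal(m$npv, 10 / 12)
  expect_equal(m$accuracy, 15 / 20)
})
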