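# Wide per-patient feature table for pCR modeling: baseline and timepoint-k
# FTV, baseline MTM, percent changes, baseline ctDNA status, pCR label.
.pcr_features <- function(cohort, timepoint, eps = 0.01) {
  cohort <- as_cohort_df(cohort)
  stopifnot(timepoint %in% c("T1", "T2", "T3"))
  t0 <- cohort[cohort$timepoint == "T0", , drop = FALSE]
  tk <- cohort[cohort$timepoint == timepoint, , drop = FALSE]
  m <- match(t0$patient_id, tk$patient_id)
  out <- data.frame(
    patient_id = t0$patient_id,
    pcr = t0$pcr,
    ftv_t0 = t0$ftv_cm3,
    ftv_tk = tk$ftv_cm3[m],
    mtm_t0 = t0$mtm_per_ml,
    mtm_tk = tk$mtm_per_ml[m],
    baseline_positive = t0$ctdna_status == "positive",
    stringsAsFactors = FALSE
  )
  out$log_ftv_t0 <- log(out$ftv_t0 + 1)
  out$ftv_relchange <- (out$ftv_tk - out$ftv_t0) / pmax(out$ftv_t0, eps)
  out$log_mtm_t0 <- ifelse(out$mtm_t0 > 0, log(out$mtm_t0), NA_real_)
  out$mtm_pctchange <- (out$mtm_tk - out$mtm_t0) / pmax(out$mtm_t0, eps)
  out
}

.fit_logistic <- function(df, features) {
  fml <- as.formula(paste("pcr ~", paste(features, collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, data = df, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100))
  )
  separated <- !fit$converged || any(abs(coef(fit)) > 15)
  list(fit = fit, separated = separated)
}

#' Fit an FTV-based logistic predictor of pathologic complete response
#'
#' A transparent two-feature logistic model of pCR at a given timepoint:
#' `log(FTV_T0 + 1)` (baseline burden) and the relative FTV change
#' `(FTV_Tk - FTV_T0) / max(FTV_T0, eps)` (early response). Fitted by
#' unpenalized maximum likelihood; complete separation is detected (by
#' non-convergence or diverging coefficients) and reported, not silently
#' regularized.
#'
#' @param train long-format cohort data frame with pCR labels and FTV at T0
#'   and `timepoint`; at least 20 complete patients with both classes.
#' @param timepoint one of "T1", "T2", "T3".
#' @param eps floor for the baseline FTV in the relative change (default
#'   0.01 cm3).
#' @return Object of class `ftv_predictor`: `timepoint`, `feature_names`,
#'   `coefficients` (including intercept), `training_ids`, `separated`,
#'   and the underlying `glm` fit.
#' @export
fit_ftv_predictor <- function(train, timepoint, eps = 0.01) {
  df <- .pcr_features(train, timepoint, eps)
  df <- df[complete.cases(df[, c("pcr", "log_ftv_t0", "ftv_relchange")]), ]
  if (nrow(df) < 20L)
    stop(sprintf("need >= 20 complete training patients, have %d", nrow(df)))
  if (length(unique(df$pcr)) < 2L)
    stop("training set contains a single pCR class")
  fl <- .fit_logistic(df, c("log_ftv_t0", "ftv_relchange"))
  if (fl$separated)
    warning("possible complete separation: coefficients diverging")
  structure(list(timepoint = timepoint,
                 feature_names = c("log_ftv_t0", "ftv_relchange"),
                 coefficients = coef(fl$fit),
                 training_ids = df$patient_id,
                 separated = fl$separated,
                 glm_fit = fl$fit),
            class = "ftv_predictor")
}

#' @export
predict.ftv_predictor <- function(object, newdata, ...) {
  df <- .pcr_features(newdata, object$timepoint)
  predict(object$glm_fit, newdata = df, type = "response")
}

#' AUC by the Mann-Whitney estimator
#'
#' Probability that a random positive scores above a random negative, with
#' ties counting one half: the area under the ROC curve.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical (or 0/1) class labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))  # 1
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified-by-label fold assignment: labels shuffled within class, then
# dealt round-robin across a running fold counter, so each fold's class mix
# matches the sample's and k = n degenerates to leave-one-out.
.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cls in unique(labels)) {
    ix <- which(labels == cls)
    ix <- ix[sample.int(length(ix))]
    fold[ix] <- (offset + seq_along(ix) - 1L) %% k + 1L
    offset <- offset + length(ix)
  }
  fold
}

#' Cross-validated AUC of FTV +/- ctDNA logistic models of pCR
#'
#' Restricted to patients ctDNA-positive at baseline, fits the FTV logistic
#' model (optionally augmented with baseline ctDNA concentration and/or its
#' percent change to the timepoint) within k pCR-stratified folds and
#' computes one AUC from the pooled out-of-fold scores.
#'
#' @param cohort long-format cohort data frame.
#' @param timepoint "T1", "T2" or "T3".
#' @param ctdna_features character subset of `c("mtm_t0", "pct_change")`;
#'   empty for the FTV-only model. Baseline concentration enters on the log
#'   scale (baseline positivity guarantees MTM_T0 > 0); percent change is on
#'   the MTM scale.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return List with `auc`, `oof_scores` (named by patient), `folds`, `n`,
#'   `n_pcr`, and `features`.
#' @export
cv_auc <- function(cohort, timepoint, ctdna_features = character(), k = 10L,
                   seed = 1L) {
  stopifnot(all(ctdna_features %in% c("mtm_t0", "pct_change")))
  feats <- c("log_ftv_t0", "ftv_relchange",
             c(mtm_t0 = "log_mtm_t0", pct_change = "mtm_pctchange")[ctdna_features])
  feats <- unname(feats)
  df <- .pcr_features(cohort, timepoint)
  df <- df[df$baseline_positive %in% TRUE, , drop = FALSE]
  df <- df[complete.cases(df[, c("pcr", feats)]), , drop = FALSE]
  if (length(unique(df$pcr)) < 2L)
    stop("both pCR classes required among baseline ctDNA-positive patients")
  k <- min(as.integer(k), nrow(df))  # k = n gives leave-one-out

  folds <- .stratified_folds(df$pcr, k, seed)
  attempt <- 0L
  repeat {
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(df$pcr[folds != f])) == 2L, logical(1)))
    if (ok) break
    attempt <- attempt + 1L
    if (attempt > 1L) stop("a training fold lacks a pCR class even after re-stratification")
    folds <- .stratified_folds(df$pcr, k, seed + 1L)
  }

  oof <- rep(NA_real_, nrow(df))
  for (f in seq_len(k)) {
    test <- folds == f
    if (!any(test)) next
    fl <- .fit_logistic(df[!test, , drop = FALSE], feats)
    oof[test] <- predict(fl$fit, newdata = df[test, , drop = FALSE],
                         type = "response")
  }
  keep <- !is.na(oof)
  list(auc = auc(oof[keep], df$pcr[keep]),
       oof_scores = setNames(oof[keep], df$patient_id[keep]),
       labels = df$pcr[keep],
       folds = folds[keep], n = sum(keep), n_pcr = sum(df$pcr[keep]),
       features = feats)
}

#' Select the ctDNA feature set with the highest cross-validated AUC
#'
#' Evaluates the four candidate ctDNA augmentations of the FTV model --
#' none, baseline concentration, percent change, or both -- by [cv_auc()]
#' and returns the best (ties broken toward fewer features).
#'
#' @inheritParams cv_auc
#' @return List with `best_features` (character, possibly empty),
#'   `auc_table` (4-row data frame of feature set and cv AUC), and
#'   `best_cv` (the winning [cv_auc()] result).
#' @export
select_combined_model <- function(cohort, timepoint, k = 10L, seed = 1L) {
  cands <- list(character(), "mtm_t0", "pct_change", c("mtm_t0", "pct_change"))
  fits <- lapply(cands, function(fs)
    cv_auc(cohort, timepoint, ctdna_features = fs, k = k, seed = seed))
  aucs <- vapply(fits, `[[`, numeric(1), "auc")
  tab <- data.frame(
    ctdna_features = vapply(cands, function(fs)
      if (length(fs) == 0L) "(none)" else paste(fs, collapse = "+"),
      character(1)),
    n_features = lengths(cands),
    cv_auc = aucs, stringsAsFactors = FALSE
  )
  best <- order(-round(aucs, 12), lengths(cands))[1]
  list(best_features = cands[[best]], auc_table = tab, best_cv = fits[[best]])
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity at every distinct score threshold (decision
#' rule: predict positive when score >= threshold), plus the trapezoidal
#' AUC, which for a step ROC equals the Mann-Whitney estimator.
#'
#' @inheritParams auc
#' @return Object of class `roc_curve`: data frame-like list with
#'   `thresholds` (decreasing, starting above the max score), `sensitivity`,
#'   `specificity`, and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (sum(labels) == 0L || sum(!labels) == 0L)
    stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc(scores, labels)),
            class = "roc_curve")
}

#' Dichotomize a model by distance to the ROC top-left corner
#'
#' Chooses the curve point minimizing the Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` to perfect classification; ties are
#' broken toward higher sensitivity.
#'
#' @param roc a [roc_curve()] object.
#' @return List with `cut` (score threshold), `sensitivity`, `specificity`,
#'   `distance`.
#' @export
dichotomize_top_left <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- order(round(d, 12), -roc$sensitivity)[1]
  list(cut = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       distance = d[best])
}

#' Predictive performance of a dichotomized classifier
#'
#' @param predicted_high logical vector: classified as high probability of
#'   pCR.
#' @param pcr logical (or 0/1) observed pCR.
#' @return List with `ppv`, `npv`, `accuracy`, `sensitivity`, `specificity`;
#'   metrics with an empty denominator are `NA`.
#' @export
#' @examples
#' classifier_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
classifier_metrics <- function(predicted_high, pcr) {
  predicted_high <- as.logical(predicted_high)
  pcr <- as.logical(pcr)
  if (length(predicted_high) != length(pcr) || length(pcr) == 0L)
    stop("inputs must be non-empty and of equal length")
  tp <- sum(predicted_high & pcr); fp <- sum(predicted_high & !pcr)
  fn <- sum(!predicted_high & pcr); tn <- sum(!predicted_high & !pcr)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       accuracy = (tp + tn) / length(pcr),
       sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp))
}
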