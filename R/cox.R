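# Per-patient survival frame from a long cohort table: T3 covariates,
# outcomes, subtype dummies (reference level HR+HER2-).
.survival_frame <- function(cohort) {
  cohort <- as_cohort_df(cohort)
  t0 <- cohort[cohort$timepoint == "T0", , drop = FALSE]
  t3 <- cohort[cohort$timepoint == "T3", , drop = FALSE]
  m <- match(t0$patient_id, t3$patient_id)
  df <- data.frame(
    patient_id = t0$patient_id,
    time = t0$drfs_years,
    event = t0$drfs_event,
    ftv_t3 = t3$ftv_cm3[m],
    ctdna_t3 = as.integer(t3$ctdna_status[m] == "positive"),
    pcr = t0$pcr,
    subtype = factor(t0$subtype, levels = c("HR+HER2-", "HER2+", "TNBC")),
    stringsAsFactors = FALSE
  )
  df[!is.na(df$time) & df$time > 0, , drop = FALSE]
}

#' Cox proportional-hazards fit for distant recurrence-free survival
#'
#' Fits DRFS on covariates measured at (or anchored to) the post-NAC
#' timepoint T3 by Cox partial likelihood with Efron tie handling.
#' Covariates are named from `ftv_t3` (continuous, cm3), `ctdna_t3` (0/1),
#' `pcr` (0/1), `subtype` (factor, reference HR+HER2-); the interaction
#' `ctdna_t3:ftv_t3` (or any `a:b` pair) may be included. Records with a
#' missing value in any requested covariate are dropped (listwise) and
#' counted.
#'
#' @param cohort long-format cohort data frame, or a per-patient data frame
#'   with columns `time`, `event` and the covariates.
#' @param covariates character vector of covariate terms, e.g.
#'   `c("ftv_t3", "ctdna_t3", "ctdna_t3:ftv_t3")`.
#' @return Object of class `cox_fit`: coefficient table (`coef`, `hr`,
#'   `ci95_lo`, `ci95_hi`, `se`, `wald_p`), `loglik` (maximized log partial
#'   likelihood), `aic`, `n`, `n_events`, `n_dropped`, and the underlying
#'   `coxph` fit.
#' @export
#' @examples
#' sc <- simulate_cohort(sim_config(n_patients = 80, seed = 4))
#' fit_cox(sc$cohort, c("ftv_t3", "ctdna_t3"))
fit_cox <- function(cohort, covariates) {
  df <- if (!is.null(cohort$time) && !is.null(cohort$event)) cohort
        else .survival_frame(cohort)
  base_vars <- unique(unlist(strsplit(covariates, ":", fixed = TRUE)))
  missing_cols <- setdiff(base_vars, names(df))
  if (length(missing_cols))
    stop("unknown covariate(s): ", paste(missing_cols, collapse = ", "))
  keep <- complete.cases(df[, c("time", "event", base_vars), drop = FALSE])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (sum(df$event) < 1L) stop("no events in the analysis set")

  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(covariates, collapse = " + ")))
  mm <- model.matrix(as.formula(paste("~", paste(covariates, collapse = "+"))),
                     data = df)
  if (qr(mm)$rank < ncol(mm)) {
    q <- qr(mm)
    bad <- colnames(mm)[-seq_len(q$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  monotone <- any(!is.finite(beta)) || any(abs(beta) > 15 & se > 100)
  if (monotone)
    warning("possible monotone likelihood: a coefficient appears unbounded")
  tab <- data.frame(
    term = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    ci95_lo = exp(unname(beta) - 1.96 * se),
    ci95_hi = exp(unname(beta) + 1.96 * se),
    se = unname(se),
    wald_p = 2 * pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(coefficients = tab,
                 loglik = ll,
                 aic = -2 * ll + 2 * length(beta),
                 n = nrow(df),
                 n_events = sum(df$event),
                 n_dropped = n_dropped,
                 covariates = covariates,
                 monotone = monotone,
                 coxph_fit = fit,
                 data = df),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d%s\n", x$n,
              x$n_events,
              if (x$n_dropped > 0)
                sprintf(" (%d dropped, incomplete covariates)", x$n_dropped)
              else ""))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("log partial likelihood = %.4f, AIC = %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$coefficients$coef, object$coefficients$term)
}

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$coefficients), class = "logLik")
}

#' Proportional-hazards diagnostic via scaled Schoenfeld residuals
#'
#' Tests, per covariate and globally, for association between the scaled
#' Schoenfeld residuals and transformed event time -- a non-zero slope
#' indicates a time-varying effect, violating proportional hazards.
#'
#' @param fit a [fit_cox()] result (needs >= 2 events).
#' @param transform time transform: "km" (Kaplan-Meier, default), "rank" or
#'   "identity".
#' @return Object of class `ph_test`: `table` (chisq, df, p per covariate
#'   plus a GLOBAL row), `global_p`, `transform`.
#' @export
ph_test <- function(fit, transform = c("km", "rank", "identity")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events < 2L) stop("need >= 2 events for the Schoenfeld test")
  z <- survival::cox.zph(fit$coxph_fit, transform = transform)
  tab <- as.data.frame(z$table)
  structure(list(table = tab,
                 global_p = tab["GLOBAL", "p"],
                 transform = transform),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat(sprintf("Schoenfeld PH test (time transform: %s)\n", x$transform))
  print(signif(as.matrix(x$table), 4))
  invisible(x)
}

# TRUE if covariate set a is nested in b (term subset).
.is_nested <- function(a, b) all(a %in% b) && length(a) < length(b)

#' Compare Cox model specifications by AIC
#'
#' Fits every specification on the common complete-case subset (the
#' intersection of complete cases over the union of covariates, so AICs are
#' comparable), and reports log likelihood, parameter count, AIC, and a
#' likelihood-ratio p-value against the largest nested parent in the list.
#'
#' @param cohort as in [fit_cox()].
#' @param model_specs named list of covariate character vectors.
#' @return Data frame sorted by AIC: `model`, `covariates`, `loglik`, `k`,
#'   `aic`, `lr_p_vs_parent`, `parent`.
#' @export
compare_models_aic <- function(cohort, model_specs) {
  df <- if (!is.null(cohort$time) && !is.null(cohort$event)) cohort
        else .survival_frame(cohort)
  all_vars <- unique(unlist(strsplit(unlist(model_specs), ":", fixed = TRUE)))
  keep <- complete.cases(df[, c("time", "event",
                                intersect(all_vars, names(df))), drop = FALSE])
  if (!any(keep))
    stop("no record is complete across the union of covariates")
  common <- df[keep, , drop = FALSE]
  if (sum(common$event) < 1L) stop("no events in the common complete-case set")

  if (is.null(names(model_specs)))
    names(model_specs) <- vapply(model_specs, paste, character(1),
                                 collapse = "+")
  fits <- lapply(model_specs, function(cv) fit_cox(common, cv))
  n_par <- vapply(fits, function(f) nrow(f$coefficients), numeric(1))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  aic <- vapply(fits, `[[`, numeric(1), "aic")

  lr_p <- rep(NA_real_, length(fits))
  parent <- rep(NA_character_, length(fits))
  for (i in seq_along(fits)) {
    nested_in_i <- which(vapply(model_specs, .is_nested, logical(1),
                                b = model_specs[[i]]))
    if (length(nested_in_i)) {
      j <- nested_in_i[which.max(n_par[nested_in_i])]
      lr <- 2 * (ll[i] - ll[j])
      dfree <- n_par[i] - n_par[j]
      if (dfree > 0) {
        lr_p[i] <- pchisq(max(lr, 0), df = dfree, lower.tail = FALSE)
        parent[i] <- names(model_specs)[j]
      }
    }
  }
  out <- data.frame(model = names(model_specs),
                    covariates = vapply(model_specs, paste, character(1),
                                        collapse = " + "),
                    loglik = ll, k = n_par, aic = aic,
                    lr_p_vs_parent = lr_p, parent = parent,
                    n = nrow(common), n_events = sum(common$event),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out
}
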