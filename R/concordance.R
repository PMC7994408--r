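#' Fisher z-transform of a correlation coefficient
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)), the variance-stabilizing
#' transform applied to per-patient Pearson correlations before averaging.
#' Correlations of exactly +/-1 (which arise from short, collinear series)
#' are clipped to +/-(1 - 1e-7) so the statistic stays finite; the number of
#' clipped values is reported by the callers that aggregate.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @return The transformed value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5493061
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Per-patient timecourses from a long cohort table
#'
#' Aligns each patient's FTV and ctDNA concentration on the T0-T3 grid
#' (missing timepoints become `NA`) and records baseline ctDNA status, the
#' eligibility gate for the trajectory-concordance test.
#'
#' @param cohort long-format cohort data frame (see [read_cohort()]).
#' @return List of class `patient_timecourses`; each element has
#'   `patient_id`, `ftv` and `mtm` (length-4, T0..T3, `NA` where missing)
#'   and `baseline_positive` (`NA` if T0 ctDNA status is unknown).
#' @export
patient_timecourses <- function(cohort) {
  cohort <- as_cohort_df(cohort)
  ids <- unique(cohort$patient_id)
  out <- lapply(ids, function(pid) {
    sub <- cohort[cohort$patient_id == pid, , drop = FALSE]
    ftv <- mtm <- rep(NA_real_, 4)
    m <- match(sub$timepoint, TIMEPOINTS)
    ftv[m] <- sub$ftv_cm3
    mtm[m] <- sub$mtm_per_ml
    st0 <- sub$ctdna_status[sub$timepoint == "T0"]
    list(patient_id = pid, ftv = ftv, mtm = mtm,
         baseline_positive = if (length(st0) == 1L && !is.na(st0))
           st0 == "positive" else NA)
  })
  names(out) <- ids
  class(out) <- "patient_timecourses"
  out
}

# Pearson r between two length-4 series over timepoints where both are
# present. Returns list(r, n_pairs, reason); r is NA when ineligible.
.pairwise_r <- function(x, y, min_timepoints) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_timepoints)
    return(list(r = NA_real_, n_pairs = n, reason = "too few points"))
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0)
    return(list(r = NA_real_, n_pairs = n, reason = "zero variance"))
  list(r = cor(xs, ys), n_pairs = n, reason = NA_character_)
}

#' Pearson correlation of one patient's FTV and ctDNA trajectories
#'
#' Computed over the timepoints where both series are observed. A patient is
#' ineligible (result `NA` with a reason) with fewer than `min_timepoints`
#' complete pairs, zero variance in either series, or a ctDNA-negative (or
#' unknown) baseline.
#'
#' @param tc one element of [patient_timecourses()] (or any list with
#'   `ftv`, `mtm`, `baseline_positive`).
#' @param min_timepoints minimum complete pairs (default 3; a 2-point
#'   correlation is always +/-1 and would distort the mean).
#' @return List with `r`, `n_pairs`, `reason` (`NA` when eligible).
#' @export
patient_trajectory_r <- function(tc, min_timepoints = 3L) {
  if (!isTRUE(tc$baseline_positive))
    return(list(r = NA_real_, n_pairs = sum(!is.na(tc$ftv) & !is.na(tc$mtm)),
                reason = "baseline negative"))
  .pairwise_r(tc$ftv, tc$mtm, min_timepoints)
}

#' Mean Fisher z-transformed trajectory correlation
#'
#' The observed statistic of the concordance test: per-patient Pearson
#' correlations between serial FTV and ctDNA concentration, Fisher
#' z-transformed (to normalize their distribution so the mean is
#' well-behaved), averaged over eligible patients.
#'
#' @param tcs a [patient_timecourses()] list.
#' @param min_timepoints see [patient_trajectory_r()].
#' @return List with `mean_z`, `n_used`, `n_clipped`, `per_patient`
#'   (data frame of patient_id, r, z, n_pairs, reason) and `excluded`
#'   (the ineligible subset of that table).
#' @export
mean_fisher_z <- function(tcs, min_timepoints = 3L) {
  rows <- lapply(tcs, function(tc) {
    res <- patient_trajectory_r(tc, min_timepoints)
    data.frame(patient_id = tc$patient_id, r = res$r,
               z = if (is.na(res$r)) NA_real_ else fisher_z(res$r),
               n_pairs = res$n_pairs, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  used <- tab[is.na(tab$reason), , drop = FALSE]
  if (nrow(used) < 2L)
    stop(sprintf("need >= 2 eligible patients, have %d; exclusions: %s",
                 nrow(used),
                 paste(sprintf("%s (%s)", tab$patient_id[!is.na(tab$reason)],
                               tab$reason[!is.na(tab$reason)]),
                       collapse = ", ")))
  list(mean_z = mean(used$z), n_used = nrow(used),
       n_clipped = sum(abs(used$r) >= 1 - 1e-7),
       per_patient = tab,
       excluded = tab[!is.na(tab$reason), , drop = FALSE])
}

# All permutations of 1..n (n <= 8), in lexicographic order.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    cbind(first, rest, deparse.level = 0)
  }))
}

#' Monte Carlo permutation test of ctDNA-FTV trajectory concordance
#'
#' Tests whether per-patient ctDNA and FTV trajectories co-vary, in the
#' subset of patients ctDNA-positive at baseline. The observed statistic is
#' the mean Fisher z-transformed Pearson correlation between each patient's
#' serial FTV and ctDNA concentrations. The null reference is built by
#' repeatedly permuting which patient's ctDNA series is paired with which
#' patient's FTV series (a uniform random permutation of patient labels;
#' fixed points are allowed), recomputing the mean z over pairings with
#' enough overlapping timepoints. The empirical two-sided p-value is the
#' add-one-corrected fraction of permutation means at least as far from the
#' center of the permutation distribution as the observed mean. The center
#' is the permutation mean by default: under random pairing the null center
#' of the statistic need not be zero, and the mean (unlike the median) is a
#' continuous functional, so exhaustive and Monte Carlo mode agree on small
#' cohorts whose discrete permutation distribution has an ambiguous median.
#'
#' @param tcs a [patient_timecourses()] list (or a cohort data frame, which
#'   is converted).
#' @param B number of Monte Carlo permutations (default 1000; a warning is
#'   issued below 100). Ignored in exhaustive mode.
#' @param seed integer seed; required, for reproducibility.
#' @param min_timepoints minimum overlapping timepoints per pairing
#'   (default 3).
#' @param exhaustive if `TRUE`, enumerate all n! pairings instead of
#'   sampling (feasible for n <= 8 eligible patients).
#' @param center centering functional for the two-sided rule: "mean"
#'   (default) or "median" of the permutation distribution.
#' @return Object of class `concordance_permutation`: `observed_mean_z`,
#'   `perm_means` (length B, or n! in exhaustive mode), `empirical_p`, `B`,
#'   `n_patients_used`, `n_clipped`, `excluded`, `seed`, `min_timepoints`,
#'   `exhaustive`.
#' @export
#' @examples
#' sc <- simulate_cohort(sim_config(n_patients = 25, seed = 3))
#' pt <- permutation_test(patient_timecourses(sc$cohort), B = 200, seed = 9)
#' pt$empirical_p
permutation_test <- function(tcs, B = 1000L, seed, min_timepoints = 3L,
                             exhaustive = FALSE,
                             center = c("mean", "median")) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required: permutation results must be reproducible")
  center <- match.arg(center)
  center_fun <- if (center == "mean") function(v) mean(v, na.rm = TRUE)
                else function(v) median(v, na.rm = TRUE)
  if (inherits(tcs, "data.frame")) tcs <- patient_timecourses(tcs)
  if (!exhaustive && B < 100)
    warning("B < 100 gives a coarse empirical p-value")

  obs <- mean_fisher_z(tcs, min_timepoints)
  used_ids <- obs$per_patient$patient_id[is.na(obs$per_patient$reason)]
  n <- length(used_ids)
  if (n < 3L)
    stop("need >= 3 eligible patients for a nontrivial permutation test")
  el <- tcs[used_ids]

  # Precompute r for every (FTV_i, MTM_j) pairing once; each permutation is
  # then just an index lookup.
  zmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- .pairwise_r(el[[i]]$ftv, el[[j]]$mtm, min_timepoints)$r
      if (!is.na(r)) zmat[i, j] <- fisher_z(r)
    }
  }

  perm_stat <- function(perm) {
    z <- zmat[cbind(seq_len(n), perm)]
    z <- z[!is.na(z)]          # pairings with too little overlap are skipped
    if (length(z) == 0L) NA_real_ else mean(z)
  }

  if (exhaustive) {
    if (n > 8L) stop("exhaustive mode is limited to 8 eligible patients")
    perms <- .all_perms(n)
    perm_means <- apply(perms, 1, perm_stat)
    B_eff <- nrow(perms)
    ctr <- center_fun(perm_means)
    dev <- abs(obs$mean_z - ctr)
    empirical_p <- mean(abs(perm_means - ctr) >= dev - 1e-12, na.rm = TRUE)
  } else {
    set.seed(seed)
    perm_means <- vapply(seq_len(B), function(b) perm_stat(sample.int(n)),
                         numeric(1))
    B_eff <- as.integer(B)
    ctr <- center_fun(perm_means)
    dev <- abs(obs$mean_z - ctr)
    empirical_p <- (1 + sum(abs(perm_means - ctr) >= dev - 1e-12,
                            na.rm = TRUE)) / (B_eff + 1)
  }

  structure(list(observed_mean_z = obs$mean_z,
                 perm_means = perm_means,
                 empirical_p = empirical_p,
                 B = B_eff,
                 n_patients_used = n,
                 n_clipped = obs$n_clipped,
                 per_patient = obs$per_patient,
                 excluded = obs$excluded,
                 seed = seed,
                 min_timepoints = min_timepoints,
                 center = center,
                 exhaustive = exhaustive),
            class = "concordance_permutation")
}

#' @export
print.concordance_permutation <- function(x, ...) {
  cat("Trajectory-concordance permutation test (mean Fisher z)\n")
  cat(sprintf("  observed mean z = %.4f over %d baseline ctDNA-positive patients\n",
              x$observed_mean_z, x$n_patients_used))
  cat(sprintf("  %s: %d pairings, empirical two-sided p = %.4g\n",
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$B, x$empirical_p))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  excluded %d patient(s): %s\n", nrow(x$excluded),
                paste(sprintf("%s (%s)", x$excluded$patient_id,
                              x$excluded$reason), collapse = ", ")))
  invisible(x)
}
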