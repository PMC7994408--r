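# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Spearman rho by explicit average-ranking + Pearson on the ranks.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Mann-Whitney U (pairs with a > b, ties 1/2) by double loop.
oracle_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
  u
}

# Exact two-sided rank-sum p by enumerating all group assignments.
oracle_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  mu <- na * length(b) / 2
  dev <- abs(oracle_u(a, b) - mu)
  combs <- combn(length(pool), na)
  hits <- 0
  for (j in seq_len(ncol(combs))) {
    ga <- pool[combs[, j]]; gb <- pool[-combs[, j]]
    if (abs(oracle_u(ga, gb) - mu) >= dev - 1e-12) hits <- hits + 1
  }
  hits / ncol(combs)
}

# AUC by O(n^2) pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  oracle_u(pos, neg) / (length(pos) * length(neg))
}

# FTV by a triple voxel loop over the ROI at a given frame.
oracle_ftv <- function(series, threshold_pct, frame) {
  roi <- series$roi_box
  count <- 0
  for (z in roi$z[1]:roi$z[2]) for (y in roi$y[1]:roi$y[2])
    for (x in roi$x[1]:roi$x[2]) {
      pre <- series$signal[1, z, y, x]
      if (pre > 0) {
        pe <- 100 * (series$signal[frame, z, y, x] - pre) / pre
        if (pe >= threshold_pct) count <- count + 1
      }
    }
  count * series$voxel_volume_cm3
}

# Cox log partial likelihood with Efron ties by explicit risk-set sums.
oracle_cox_loglik <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(w[R]); sum_d <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}

# Trapezoidal area under an roc_curve object's (1 - spec, sens) polyline.
oracle_trapezoid_auc <- function(roc) {
  x <- 1 - roc$specificity; y <- roc$sensitivity
  o <- order(x, y)
  x <- c(0, x[o], 1); y <- c(0, y[o], 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

# Minimal hand-built timecourse.
make_tc <- function(ftv, mtm, baseline_positive = TRUE, id = "P1") {
  list(patient_id = id, ftv = ftv, mtm = mtm,
       baseline_positive = baseline_positive)
}

# Timecourse list with a documented concordance structure: shared latent
# trend when `concordant`, independent trends otherwise.
make_tc_cohort <- function(n, concordant = TRUE, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    trend <- rnorm(1, 0.8, 0.5)
    ftv <- exp(3 - trend * (0:3) + rnorm(4, 0, 0.3))
    trend2 <- if (concordant) trend else rnorm(1, 0.8, 0.5)
    mtm <- exp(1 + -trend2 * (0:3) + rnorm(4, 0, 0.3))
    make_tc(ftv, mtm, TRUE, sprintf("P%03d", i))
  })
  names(out) <- vapply(out, `[[`, character(1), "patient_id")
  class(out) <- "patient_timecourses"
  out
}

# Wide synthetic pCR data with a known logistic law, expressed as a minimal
# long-format cohort (T0 + T1 rows, everyone ctDNA-positive at baseline).
make_pcr_cohort <- function(n, b0 = 0.5, b1 = -0.8, b2 = -2, seed = 1,
                            informative_ctdna = FALSE, null_labels = FALSE) {
  set.seed(seed)
  ftv0 <- exp(rnorm(n, 3, 1))
  relch <- pmax(rnorm(n, -0.5, 0.4), -1)
  ftv1 <- ftv0 * (1 + relch)
  mtm0 <- exp(rnorm(n, 1, 1.5))
  mtm1 <- mtm0 * exp(rnorm(n, -0.5, 0.7))
  eta <- b0 + b1 * log(ftv0 + 1) + b2 * relch
  if (informative_ctdna) eta <- eta - 1.2 * log(mtm0)
  pcr <- if (null_labels) rbinom(n, 1, 0.35) else rbinom(n, 1, plogis(eta))
  data.frame(
    patient_id = rep(sprintf("S%05d", seq_len(n)), times = 2),
    timepoint = rep(c("T0", "T1"), each = n),
    ftv_cm3 = c(ftv0, ftv1),
    mtm_per_ml = c(mtm0, mtm1),
    ctdna_status = "positive",
    pcr = rep(pcr, 2),
    stringsAsFactors = FALSE
  )
}
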