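#' Spearman rank correlation with large-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks (average
#' ranks for ties) and a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, and `n`. If either vector has zero rank
#'   variance (all values tied), `rho` and `p` are `NA` and `degenerate`
#'   is `TRUE`.
#' @export
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))$rho  # 1
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values must be removed upstream")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

# U statistic (number of (a, b) pairs with a > b, ties counting 1/2)
.u_stat <- function(a, b) {
  ra <- rank(c(a, b))[seq_along(a)]
  sum(ra) - length(a) * (length(a) + 1) / 2
}

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples by the Mann-Whitney U
#' statistic. When both groups have at most `exact_max` observations the
#' p-value is computed by exhaustive enumeration of all group assignments
#' (valid under ties); otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_max largest per-group size for the exact branch (default 8).
#' @return List with `statistic` (U for group `a`), `p`, and `method`.
#' @export
#' @examples
#' ranksum_test(c(1, 2, 3), c(10, 11, 12))$p  # 0.1
ranksum_test <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values must be removed upstream")
  na <- length(a); nb <- length(b)
  u <- .u_stat(a, b)
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    pool <- c(a, b)
    combs <- combn(na + nb, na)
    dev <- abs(u - mu)
    us <- apply(combs, 2, function(ix) .u_stat(pool[ix], pool[-ix]))
    p <- mean(abs(us - mu) >= dev - 1e-12)
    return(list(statistic = u, p = p, method = "exact enumeration"))
  }
  # tie-corrected normal approximation (continuity-corrected)
  nt <- na + nb
  ties <- table(c(a, b))
  sigma2 <- na * nb / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sigma2 <= 0)
    return(list(statistic = u, p = NA_real_, method = "degenerate (all tied)"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = u, p = p, method = "normal approximation")
}

#' Cross-sectional ctDNA-FTV association at each timepoint
#'
#' For each timepoint, pairs FTV with ctDNA concentration (MTM/mL, zeros for
#' ctDNA-negative samples included) across patients with both measurements,
#' and reports the Spearman correlation plus a rank-sum comparison of FTV
#' between ctDNA-positive and ctDNA-negative patients.
#'
#' @param cohort a long-format cohort data frame (see [read_cohort()]).
#' @param timepoints timepoints to evaluate (default T0-T3).
#' @return Data frame with one row per timepoint: `timepoint`, `n_pairs`,
#'   `n_dropped`, `rho`, `rho_p`, `median_ftv_pos`, `median_ftv_neg`,
#'   `ranksum_p`, `reason` (`NA` when all statistics are defined).
#' @export
association_by_timepoint <- function(cohort, timepoints = TIMEPOINTS) {
  cohort <- as_cohort_df(cohort)
  out <- lapply(timepoints, function(tp) {
    sub <- cohort[cohort$timepoint == tp, , drop = FALSE]
    ok <- !is.na(sub$ftv_cm3) & !is.na(sub$mtm_per_ml) & !is.na(sub$ctdna_status)
    n_dropped <- sum(!ok)
    sub <- sub[ok, , drop = FALSE]
    row <- data.frame(timepoint = tp, n_pairs = nrow(sub),
                      n_dropped = n_dropped,
                      rho = NA_real_, rho_p = NA_real_,
                      median_ftv_pos = NA_real_, median_ftv_neg = NA_real_,
                      ranksum_p = NA_real_, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (nrow(sub) < 3L) {
      row$reason <- "fewer than 3 complete pairs"
      return(row)
    }
    sp <- spearman_rho(sub$ftv_cm3, sub$mtm_per_ml)
    if (isTRUE(sp$degenerate)) {
      row$reason <- "zero rank variance"
    } else {
      row$rho <- sp$rho; row$rho_p <- sp$p
    }
    pos <- sub$ftv_cm3[sub$ctdna_status == "positive"]
    neg <- sub$ftv_cm3[sub$ctdna_status == "negative"]
    if (length(pos) == 0L || length(neg) == 0L) {
      row$reason <- paste(c(row$reason[!is.na(row$reason)],
                            "single ctDNA status group"), collapse = "; ")
      row$median_ftv_pos <- if (length(pos)) median(pos) else NA_real_
      row$median_ftv_neg <- if (length(neg)) median(neg) else NA_real_
    } else {
      row$median_ftv_pos <- median(pos)
      row$median_ftv_neg <- median(neg)
      row$ranksum_p <- ranksum_test(pos, neg)$p
    }
    row
  })
  do.call(rbind, out)
}
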