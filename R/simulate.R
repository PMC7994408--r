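#' Simulation configuration for a synthetic neoadjuvant cohort
#'
#' Collects and validates the parameters of the synthetic-cohort generator.
#' Defaults emulate a high-risk early breast cancer neoadjuvant trial cohort
#' followed over four serial timepoints (T0 pretreatment, T1 early-taxane,
#' T2 inter-regimen, T3 post-NAC pre-surgery): 84 patients, subtype mix
#' 35/23/43% (HR+HER2-, HER2+, TNBC), ctDNA-FTV rank correlation about
#' 0.45 among ctDNA-positive samples, a 27% pathologic complete response
#' rate, 63% baseline ctDNA positivity, and an 11.5-fold distant-recurrence
#' hazard for patients ctDNA-positive after NAC.
#'
#' @param n_patients number of patients (>= 4).
#' @param subtype_probs length-3 probability vector (HR+HER2-, HER2+, TNBC),
#'   must sum to 1 within 1e-12.
#' @param rho_target target Spearman correlation, in (0, 1), between FTV and
#'   ctDNA concentration among detectable (ctDNA-positive) samples at a
#'   cross-section.
#' @param pcr_rate_target target marginal pCR proportion, in (0, 1).
#' @param hr_ctdna_t3 hazard multiplier (> 0) on distant recurrence/death for
#'   ctDNA positivity at T3.
#' @param log_hr_ftv_per_cm3 log hazard ratio per cm3 of T3 functional tumor
#'   volume.
#' @param detection_threshold_mtm assay detection limit in mean tumor
#'   molecules per mL plasma (MTM/mL, >= 0); concentrations below it are
#'   reported as 0 with negative status.
#' @param baseline_pos_rate target proportion of patients ctDNA-positive at
#'   T0, in (0, 1).
#' @param missing_rate probability, in \[0, 1), that each of T1-T3 is missing
#'   for a patient; baseline T0 is never missing.
#' @param censor_horizon_years upper bound (> 0) of the uniform censoring
#'   distribution, in years.
#' @param seed integer seed driving all randomness; each patient draws from
#'   a deterministic substream so extending the cohort never perturbs
#'   earlier patients.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 40, seed = 7)
sim_config <- function(n_patients = 84L,
                       subtype_probs = c(29, 19, 36) / 84,
                       rho_target = 0.45,
                       pcr_rate_target = 23 / 84,
                       hr_ctdna_t3 = 11.5,
                       log_hr_ftv_per_cm3 = log(1.03),
                       detection_threshold_mtm = 0.1,
                       baseline_pos_rate = 53 / 84,
                       missing_rate = 0.15,
                       censor_horizon_years = 6.3,
                       seed = 1L) {
  if (!is_count(n_patients) || n_patients < 4)
    stop_field("n_patients", "must be a single integer >= 4")
  if (!is.numeric(subtype_probs) || length(subtype_probs) != 3L ||
      any(!is.finite(subtype_probs)) || any(subtype_probs < 0))
    stop_field("subtype_probs", "must be 3 non-negative probabilities")
  if (abs(sum(subtype_probs) - 1) > 1e-12)
    stop_field("subtype_probs", "must sum to 1 within 1e-12")
  if (!is_prob(rho_target) || rho_target <= 0 || rho_target >= 1)
    stop_field("rho_target", "must lie strictly in (0, 1)")
  if (!is_prob(pcr_rate_target) || pcr_rate_target <= 0 || pcr_rate_target >= 1)
    stop_field("pcr_rate_target", "must lie strictly in (0, 1)")
  if (!is.numeric(hr_ctdna_t3) || length(hr_ctdna_t3) != 1L ||
      !is.finite(hr_ctdna_t3) || hr_ctdna_t3 <= 0)
    stop_field("hr_ctdna_t3", "must be a single positive number")
  if (!is.numeric(log_hr_ftv_per_cm3) || length(log_hr_ftv_per_cm3) != 1L ||
      !is.finite(log_hr_ftv_per_cm3))
    stop_field("log_hr_ftv_per_cm3", "must be a single finite number")
  if (!is.numeric(detection_threshold_mtm) ||
      length(detection_threshold_mtm) != 1L ||
      !is.finite(detection_threshold_mtm) || detection_threshold_mtm < 0)
    stop_field("detection_threshold_mtm", "must be a single number >= 0")
  if (!is_prob(baseline_pos_rate) || baseline_pos_rate <= 0 ||
      baseline_pos_rate >= 1)
    stop_field("baseline_pos_rate", "must lie strictly in (0, 1)")
  if (!is_prob(missing_rate) || missing_rate >= 1)
    stop_field("missing_rate", "must lie in [0, 1)")
  if (!is.numeric(censor_horizon_years) || length(censor_horizon_years) != 1L ||
      !is.finite(censor_horizon_years) || censor_horizon_years <= 0)
    stop_field("censor_horizon_years", "must be a single positive number")
  if (!is_count(seed))
    stop_field("seed", "must be a single integer")

  cfg <- list(
    n_patients = as.integer(n_patients),
    subtype_probs = as.numeric(subtype_probs),
    rho_target = rho_target,
    pcr_rate_target = pcr_rate_target,
    hr_ctdna_t3 = hr_ctdna_t3,
    log_hr_ftv_per_cm3 = log_hr_ftv_per_cm3,
    detection_threshold_mtm = detection_threshold_mtm,
    baseline_pos_rate = baseline_pos_rate,
    missing_rate = missing_rate,
    censor_horizon_years = censor_horizon_years,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# ---------------------------------------------------------------------------
# Fixed generative constants (documented in the methods vignette; echoed in
# the truth record so downstream code never has to guess them).
.sim_constants <- function() {
  list(
    mu_log_ftv0 = 3.0,    # median baseline FTV ~ 20 cm3
    sd_log_ftv0 = 1.0,    # between-patient spread of baseline burden
    mu_resp = 0.8,        # mean per-cycle log-FTV decline (response factor)
    sd_resp = 0.5,
    sd_eps_ftv = 0.3,     # measurement/biology noise on log FTV per timepoint
    sd_shed = 1.0,        # patient-level ctDNA shedding propensity (log scale)
    c1_pcr = 2.0,         # pCR log-odds per unit response factor
    h0 = 0.015,           # baseline DRFS hazard per year (ctDNA-negative)
    age_mean = 49.3, age_sd = 11, age_range = c(25, 73),
    p_arm_mk2206 = 52 / 84,
    p_t34_given_obs = 23 / 78, p_stage_t_missing = 6 / 84,
    p_npos_given_obs = 35 / 74, p_stage_n_missing = 10 / 84,
    p_g3_given_obs = 34 / 56, p_grade_missing = 28 / 84,
    p_mp_high2 = 51 / 84
  )
}

# Population Spearman (grade) correlation between X and the zero-inflated Y:
# (X*, Y*) standard bivariate normal with correlation rho; Y is reported as 0
# (one tied block at the floor, midranked) when Y* < alpha. This is the
# large-n limit of the midrank sample Spearman on (FTV, MTM) with negatives
# at the detection floor.
.zero_inflated_spearman <- function(rho, alpha) {
  s <- sqrt(2 - rho^2)
  cond_mean_u <- function(y) pnorm(rho * y / s)   # E[Phi(X) | Y* = y]
  e1 <- integrate(function(y) pnorm(y) * cond_mean_u(y) * dnorm(y),
                  lower = alpha, upper = Inf, rel.tol = 1e-10)$value
  p0 <- pnorm(alpha)
  e2 <- if (p0 > 0)
    integrate(function(y) cond_mean_u(y) * dnorm(y),
              lower = -Inf, upper = alpha, rel.tol = 1e-10)$value
  else 0
  12 * (e1 + p0 / 2 * e2) - 3
}

# Latent bivariate-normal Pearson correlation whose zero-inflated Spearman
# equals rho_target, given the baseline positivity rate (which fixes the
# standardized detection threshold alpha).
.latent_rho <- function(rho_target, baseline_pos_rate) {
  alpha <- qnorm(1 - baseline_pos_rate)
  uniroot(function(rho) .zero_inflated_spearman(rho, alpha) - rho_target,
          interval = c(1e-6, 1 - 1e-6), tol = 1e-9)$root
}

# Intercept of the pCR logistic link so the marginal rate hits the target.
.solve_pcr_intercept <- function(target, c1, mu_r, sd_r) {
  marginal <- function(c0) {
    integrate(function(r) plogis(c0 + c1 * r) * dnorm(r, mu_r, sd_r),
              lower = mu_r - 8 * sd_r, upper = mu_r + 8 * sd_r)$value - target
  }
  uniroot(marginal, c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic serial ctDNA + FTV cohort
#'
#' Draws a cohort under a documented generative model: per patient, a latent
#' baseline log tumor burden and a latent response factor drive declining
#' log FTV across T0-T3; log ctDNA concentration (MTM/mL) tracks log FTV
#' plus a patient-level shedding factor and sample noise, calibrated so the
#' rank correlation among detectable samples is about `rho_target`;
#' concentrations below the detection limit are zeroed and flagged negative;
#' pCR follows a logistic model in the response factor with intercept solved
#' so the marginal rate is about `pcr_rate_target`; distant recurrence-free
#' survival is exponential with hazard
#' `h0 * exp(log(hr_ctdna_t3) * ctDNA_T3 + log_hr_ftv_per_cm3 * FTV_T3)`,
#' censored uniformly on (0, `censor_horizon_years`]. T1-T3 rows are dropped
#' completely at random at `missing_rate`; T0 is never missing.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{cohort}{long-format data frame, one row per patient per observed
#'       timepoint, with per-patient covariates and outcomes repeated
#'       (columns: patient_id, timepoint, ftv_cm3, mtm_per_ml, ctdna_status,
#'       age, treatment_arm, subtype, ct_stage, cn_stage, grade, mammaprint,
#'       pcr, drfs_years, drfs_event).}
#'     \item{truth}{list with the exact config, the derived generative
#'       constants, and a per-patient data frame of latent factors and
#'       noiseless state (including pre-missingness FTV/MTM at every
#'       timepoint and the true T3 ctDNA status and hazard).}
#'   }
#' @export
#' @examples
#' sc <- simulate_cohort(sim_config(n_patients = 30, seed = 2))
#' head(sc$cohort)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  k <- .sim_constants()

  sd_lf <- sqrt(k$sd_log_ftv0^2 + k$sd_eps_ftv^2)  # sd of observed log FTV_T0
  rho_lat <- .latent_rho(config$rho_target, config$baseline_pos_rate)
  # total log-MTM noise variance implied by the latent correlation
  var_extra <- sd_lf^2 * (1 / rho_lat^2 - 1)
  sd_eps_mtm2 <- var_extra - k$sd_shed^2
  if (sd_eps_mtm2 <= 0)
    stop_field("rho_target",
               "too high to calibrate given the shedding-factor variance")
  sd_eps_mtm <- sqrt(sd_eps_mtm2)
  sd_log_mtm0 <- sd_lf / rho_lat
  thr <- config$detection_threshold_mtm
  log_thr <- if (thr > 0) log(thr) else -Inf
  # intercept of log MTM so that P(MTM_T0 >= threshold) = baseline_pos_rate
  a0 <- log_thr - qnorm(1 - config$baseline_pos_rate) * sd_log_mtm0 -
    k$mu_log_ftv0
  c0 <- .solve_pcr_intercept(config$pcr_rate_target, k$c1_pcr,
                             k$mu_resp, k$sd_resp)
  # clinical T stage tied to observed baseline FTV (larger tumors -> T3/T4)
  stage_t_cut <- k$mu_log_ftv0 +
    qnorm(1 - k$p_t34_given_obs) * sqrt(sd_lf^2 + 0.8^2)

  subtypes <- c("HR+HER2-", "HER2+", "TNBC")
  n <- config$n_patients
  pts <- vector("list", n)
  long <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    subtype <- sample(subtypes, 1L, prob = config$subtype_probs)
    age <- round(min(max(rnorm(1, k$age_mean, k$age_sd), k$age_range[1]),
                     k$age_range[2]))
    arm <- if (runif(1) < k$p_arm_mk2206) "paclitaxel+MK-2206" else "paclitaxel"
    mammaprint <- if (runif(1) < k$p_mp_high2) "High2" else "High1"
    grade <- if (runif(1) < k$p_grade_missing) NA_character_
             else if (runif(1) < k$p_g3_given_obs) "III" else "II"
    cn_stage <- if (runif(1) < k$p_stage_n_missing) NA_character_
                else if (runif(1) < k$p_npos_given_obs) "positive" else "negative"

    b0 <- rnorm(1, k$mu_log_ftv0, k$sd_log_ftv0)
    r <- rnorm(1, k$mu_resp, k$sd_resp)
    u <- rnorm(1, 0, k$sd_shed)
    eps_f <- rnorm(4, 0, k$sd_eps_ftv)
    eps_m <- rnorm(4, 0, sd_eps_mtm)
    log_ftv <- b0 - r * (0:3) + eps_f
    ftv <- exp(log_ftv)
    log_mtm <- a0 + u + log_ftv + eps_m
    mtm <- exp(log_mtm)
    positive <- mtm >= thr
    mtm_obs <- ifelse(positive, mtm, 0)

    ct_stage <- if (runif(1) < k$p_stage_t_missing) NA_character_
                else if (log_ftv[1] + rnorm(1, 0, 0.8) > stage_t_cut) "T3/T4"
                else "T1/T2"

    pcr <- as.integer(runif(1) < plogis(c0 + k$c1_pcr * r))

    haz <- k$h0 * exp(log(config$hr_ctdna_t3) * positive[4] +
                      config$log_hr_ftv_per_cm3 * ftv[4])
    t_event <- rexp(1, rate = haz)
    t_cens <- runif(1, 0, config$censor_horizon_years)
    drfs_years <- min(t_event, t_cens)
    drfs_event <- as.integer(t_event <= t_cens)

    present <- c(TRUE, runif(3) >= config$missing_rate)

    pid <- sprintf("P%04d", i)
    pts[[i]] <- data.frame(
      patient_id = pid, b0 = b0, response = r, shedding = u,
      ftv_T0 = ftv[1], ftv_T1 = ftv[2], ftv_T2 = ftv[3], ftv_T3 = ftv[4],
      mtm_T0 = mtm[1], mtm_T1 = mtm[2], mtm_T2 = mtm[3], mtm_T3 = mtm[4],
      positive_T0 = positive[1], positive_T3 = positive[4],
      hazard = haz, stringsAsFactors = FALSE
    )
    long[[i]] <- data.frame(
      patient_id = pid,
      timepoint = TIMEPOINTS[present],
      ftv_cm3 = ftv[present],
      mtm_per_ml = mtm_obs[present],
      ctdna_status = ifelse(positive[present], "positive", "negative"),
      age = age, treatment_arm = arm, subtype = subtype,
      ct_stage = ct_stage, cn_stage = cn_stage, grade = grade,
      mammaprint = mammaprint, pcr = pcr,
      drfs_years = drfs_years, drfs_event = drfs_event,
      stringsAsFactors = FALSE
    )
  }

  cohort <- do.call(rbind, long)
  rownames(cohort) <- NULL
  truth <- list(
    config = config,
    derived = list(rho_latent = rho_lat, sd_eps_mtm = sd_eps_mtm,
                   mtm_intercept = a0, pcr_intercept = c0,
                   constants = k),
    patients = do.call(rbind, pts)
  )
  rownames(truth$patients) <- NULL
  out <- list(cohort = cohort, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(unique(x$cohort$patient_id))
  cat(sprintf("Synthetic NAC cohort: %d patients, %d patient-timepoint rows\n",
              n, nrow(x$cohort)))
  cat(sprintf("  seed %d | target rho %.2f | target pCR %.2f | HR(ctDNA T3) %.2f\n",
              x$truth$config$seed, x$truth$config$rho_target,
              x$truth$config$pcr_rate_target, x$truth$config$hr_ctdna_t3))
  invisible(x)
}

#' Generate a 4D DCE-MRI phantom with a known enhancing lesion
#'
#' Builds a synthetic dynamic contrast-enhanced series: a constant
#' pre-contrast background, a spherical (or exact-voxel-count) lesion whose
#' post-contrast signal follows a specified percent-enhancement curve, and
#' optional additive Gaussian noise. The noiseless above-threshold voxel
#' count at the evaluation frame is recorded as ground truth, so functional
#' tumor volume recovery can be checked exactly.
#'
#' @param shape integer vector (t, z, y, x), t >= 2; the first frame is
#'   pre-contrast.
#' @param voxel_volume_cm3 volume of one voxel in cm3 (> 0).
#' @param lesion_spec list with `center` (z, y, x; 1-based voxel indices) and
#'   either `radius` (voxels, sphere) or `n_voxels` (the lesion is the
#'   n nearest voxels to the center); `pe_pct` peak percent enhancement
#'   (default 150); optional `pe_curve`, a length-t vector of percent
#'   enhancement per frame (first entry must be 0) overriding the default
#'   plateau at `pe_pct`. Use `NULL` for a lesion-free phantom.
#' @param seed integer seed for the noise draws.
#' @param acquisition_times_s frame times in seconds; default an evenly
#'   spaced grid starting at 0 with 75 s spacing.
#' @param noise_sd additive Gaussian noise standard deviation in signal units
#'   (default 0).
#' @param s0 pre-contrast background signal (default 100).
#' @param threshold_pct enhancement threshold (percent) used for the recorded
#'   ground-truth voxel count (default 70).
#' @param eval_time_s evaluation time for the ground truth (default 150 s;
#'   nearest-frame rule).
#' @return A [dce_series()] object; attribute `truth` holds
#'   `n_lesion_voxels`, `true_n_above_threshold` and `true_ftv_cm3`.
#' @export
#' @examples
#' ph <- simulate_dce_phantom(c(3, 12, 12, 12), 0.01,
#'   lesion_spec = list(center = c(6, 6, 6), n_voxels = 100, pe_pct = 150),
#'   seed = 1)
#' attr(ph, "truth")$true_ftv_cm3
simulate_dce_phantom <- function(shape, voxel_volume_cm3, lesion_spec = NULL,
                                 seed = 1L, acquisition_times_s = NULL,
                                 noise_sd = 0, s0 = 100,
                                 threshold_pct = 70, eval_time_s = 150) {
  if (length(shape) != 4L || any(shape < 1) || any(shape != round(shape)))
    stop("'shape' must be 4 positive integers (t, z, y, x)")
  if (shape[1] < 2L) stop("need at least 2 frames (first is pre-contrast)")
  shape <- as.integer(shape)
  nt <- shape[1]
  if (is.null(acquisition_times_s))
    acquisition_times_s <- seq(0, by = 75, length.out = nt)

  mask <- array(FALSE, dim = shape[2:4])
  if (!is.null(lesion_spec)) {
    ctr <- lesion_spec$center
    if (is.null(ctr) || length(ctr) != 3L)
      stop("lesion_spec$center must be 3 voxel indices (z, y, x)")
    if (any(ctr < 1) || any(ctr > shape[2:4]))
      stop("lesion exceeds array bounds")
    idx <- expand.grid(z = seq_len(shape[2]), y = seq_len(shape[3]),
                       x = seq_len(shape[4]))
    d2 <- (idx$z - ctr[1])^2 + (idx$y - ctr[2])^2 + (idx$x - ctr[3])^2
    if (!is.null(lesion_spec$n_voxels)) {
      nv <- lesion_spec$n_voxels
      if (nv > prod(shape[2:4])) stop("lesion exceeds array bounds")
      sel <- order(d2)[seq_len(nv)]
    } else {
      rad <- lesion_spec$radius %||% 3
      if (any(ctr - rad < 1) || any(ctr + rad > shape[2:4]))
        stop("lesion exceeds array bounds")
      sel <- which(d2 <= rad^2)
    }
    mask[cbind(idx$z[sel], idx$y[sel], idx$x[sel])] <- TRUE
  }

  pe_pct <- if (!is.null(lesion_spec)) lesion_spec$pe_pct %||% 150 else 0
  pe_curve <- if (!is.null(lesion_spec) && !is.null(lesion_spec$pe_curve)) {
    pc <- lesion_spec$pe_curve
    if (length(pc) != nt || pc[1] != 0)
      stop("lesion_spec$pe_curve must have one entry per frame, first = 0")
    pc
  } else {
    c(0, rep(pe_pct, nt - 1))
  }

  set.seed(seed)
  signal <- array(s0, dim = shape)
  for (f in seq_len(nt)) {
    frame <- array(s0, dim = shape[2:4])
    frame[mask] <- s0 * (1 + pe_curve[f] / 100)
    if (noise_sd > 0)
      frame <- frame + array(rnorm(prod(shape[2:4]), 0, noise_sd),
                             dim = shape[2:4])
    frame[frame < 0] <- 0
    signal[f, , , ] <- frame
  }

  series <- dce_series(signal, acquisition_times_s, voxel_volume_cm3)
  post <- which.min(abs(acquisition_times_s[-1] - eval_time_s)) + 1L
  n_true <- sum(mask) * (pe_curve[post] >= threshold_pct)
  attr(series, "truth") <- list(
    n_lesion_voxels = sum(mask),
    true_n_above_threshold = as.integer(n_true),
    true_ftv_cm3 = n_true * voxel_volume_cm3,
    threshold_pct = threshold_pct,
    eval_frame = post
  )
  series
}
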