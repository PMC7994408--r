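# Per-patient survival frames with known exponential hazards.
make_surv <- function(n, log_hr_x = 0, log_hr_z = 0, h0 = 0.1,
                      cens_horizon = 50, seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.4)
  z <- rnorm(n, 0, 1)
  haz <- h0 * exp(log_hr_x * x + log_hr_z * z)
  t_ev <- rexp(n, haz)
  t_c <- runif(n, 0, cens_horizon)
  data.frame(patient_id = sprintf("P%05d", seq_len(n)),
             time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
             x = x, z = z)
}

test_that("null covariates are recovered near zero, true effects within 3 SE", {
  df <- make_surv(2000, log_hr_x = 0, log_hr_z = 0.5, seed = 2)
  fit <- fit_cox(df, c("x", "z"))
  tab <- fit$coefficients
  expect_lt(abs(tab$coef[tab$term == "x"]), 3 * tab$se[tab$term == "x"])
  expect_lt(abs(tab$coef[tab$term == "z"] - 0.5),
            3 * tab$se[tab$term == "z"])
})

test_that("a two-group exponential simulation recovers HR 11.5 on the log scale", {
  df <- make_surv(2000, log_hr_x = log(11.5), h0 = 0.02, seed = 3)
  fit <- fit_cox(df, "x")
  tab <- fit$coefficients
  expect_lt(abs(tab$coef[1] - log(11.5)), 3 * tab$se[1])
  expect_equal(tab$hr, exp(tab$coef))
  expect_equal(tab$ci95_lo, exp(tab$coef - 1.96 * tab$se))
})

test_that("log partial likelihood matches the explicit risk-set oracle", {
  for (seed in 1:3) {
    df <- make_surv(25, log_hr_x = 0.7, log_hr_z = -0.4, h0 = 0.3,
                    seed = seed)
    # duplicate a few times to force ties under Efron handling
    df$time <- round(df$time, 1) + 0.05
    fit <- fit_cox(df, c("x", "z"))
    X <- as.matrix(df[, c("x", "z")])
    beta <- coef(fit)
    expect_equal(fit$loglik, oracle_cox_loglik(beta, df$time, df$event, X),
                 tolerance = 1e-10)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * length(beta))
  }
})

test_that("duplicating every record preserves the Breslow partial likelihood exactly", {
  df <- make_surv(40, log_hr_x = 0.8, seed = 5)
  df$time <- df$time + seq_len(40) * 1e-6   # tie-free original data
  dup <- rbind(df, transform(df, patient_id = paste0(patient_id, "d")))
  f1 <- fit_cox(df, "x")
  # duplication creates ties; the exact 2x-loglik identity is a property of
  # the Breslow likelihood, which coincides with Efron on the tie-free data
  b1 <- survival::coxph(survival::Surv(time, event) ~ x, df, ties = "breslow")
  b2 <- survival::coxph(survival::Surv(time, event) ~ x, dup, ties = "breslow")
  expect_equal(coef(f1)[["x"]], unname(coef(b1)), tolerance = 1e-7)
  expect_equal(unname(coef(b2)), unname(coef(b1)), tolerance = 1e-7)
  # risk sets double, so each of the D events contributes an extra -2 log 2
  expect_equal(b2$loglik[2], 2 * b1$loglik[2] - 2 * log(2) * sum(df$event),
               tolerance = 1e-8)
  # Efron's tie correction on the duplicated data stays close
  f2 <- fit_cox(dup, "x")
  expect_equal(f2$coefficients$coef, f1$coefficients$coef, tolerance = 0.05)
})

test_that("rescaling a covariate rescales its coefficient and nothing else", {
  df <- make_surv(300, log_hr_z = 0.6, seed = 6)
  f1 <- fit_cox(df, "z")
  df2 <- transform(df, z = z * 10)
  f2 <- fit_cox(df2, "z")
  expect_equal(f1$coefficients$coef, 10 * f2$coefficients$coef,
               tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
  expect_equal(f1$coefficients$wald_p, f2$coefficients$wald_p,
               tolerance = 1e-6)
})

test_that("degenerate designs and event-free data are refused", {
  df <- make_surv(50, seed = 7)
  df$event <- 0
  expect_error(fit_cox(df, "x"), "no events")
  df2 <- make_surv(50, seed = 8)
  df2$x2 <- 2 * df2$x
  expect_error(fit_cox(df2, c("x", "x2")), "collinear")
  expect_error(fit_cox(df2, "nope"), "unknown covariate")
})

test_that("interaction fit includes the product term on the cohort surface", {
  sc <- simulate_cohort(sim_config(n_patients = 200, seed = 10))
  fit <- fit_cox(sc$cohort, c("ftv_t3", "ctdna_t3", "ctdna_t3:ftv_t3"))
  expect_setequal(fit$coefficients$term,
                  c("ftv_t3", "ctdna_t3", "ftv_t3:ctdna_t3"))
  # the product column really is elementwise ftv * ctdna
  mm <- model.matrix(fit$coxph_fit)
  expect_equal(unname(mm[, "ftv_t3:ctdna_t3"]),
               unname(mm[, "ftv_t3"] * mm[, "ctdna_t3"]))
})

test_that("Schoenfeld diagnostic is calibrated under PH and powered against it", {
  # calibration: proportional hazards truth
  global_p <- vapply(1:400, function(i) {
    df <- make_surv(150, log_hr_x = 0.7, h0 = 0.15, seed = 2000 + i)
    ph_test(fit_cox(df, "x"))$global_p
  }, numeric(1))
  expect_gte(mean(global_p <= 0.05), 0.03)
  expect_lte(mean(global_p <= 0.05), 0.08)

  # power: effect reverses sign at the median event time
  rej <- vapply(1:40, function(i) {
    set.seed(3000 + i)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    t1 <- rexp(n, 0.2 * exp(1.5 * x))        # early: strong positive effect
    flip <- t1 > 3
    t_obs <- ifelse(flip, 3 + rexp(n, 0.2 * exp(-1.5 * x)), t1)
    df <- data.frame(patient_id = as.character(seq_len(n)),
                     time = pmin(t_obs, 12),
                     event = as.integer(t_obs <= 12), x = x)
    ph_test(fit_cox(df, "x"))$global_p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)

  # single covariate: global test equals the per-covariate test
  df <- make_surv(200, log_hr_x = 0.5, seed = 11)
  pt <- ph_test(fit_cox(df, "x"))
  expect_equal(pt$table["x", "p"], pt$global_p, tolerance = 1e-6)
})

test_that("Efron and Breslow partial likelihoods coincide on tie-free data", {
  df <- make_surv(60, log_hr_x = 0.6, seed = 12)
  df$time <- df$time + seq_len(60) * 1e-7
  fit <- fit_cox(df, "x")
  bres <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                          ties = "breslow")
  expect_equal(fit$loglik, bres$loglik[2], tolerance = 1e-8)
  expect_equal(fit$coefficients$coef, unname(coef(bres)), tolerance = 1e-6)
})

test_that("AIC comparison runs on a common subset and penalizes noise covariates", {
  sc <- simulate_cohort(sim_config(n_patients = 150, seed = 13))
  specs <- list(base = c("pcr", "subtype"),
                ftv = c("pcr", "subtype", "ftv_t3"),
                full = c("pcr", "subtype", "ftv_t3", "ctdna_t3"))
  tab <- compare_models_aic(sc$cohort, specs)
  expect_identical(length(unique(tab$n)), 1L)
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$k)
  # nesting: loglik non-decreasing with added covariates
  ll <- setNames(tab$loglik, tab$model)
  expect_gte(ll["ftv"], ll["base"] - 1e-9)
  expect_gte(ll["full"], ll["ftv"] - 1e-9)
  expect_identical(tab$parent[tab$model == "full"], "ftv")

  # pure-noise covariate: median AIC increase near 2 - median(chisq_1)
  daic <- vapply(1:400, function(i) {
    df <- make_surv(120, log_hr_x = 0.6, h0 = 0.2, seed = 4000 + i)
    df$noise <- rnorm(120)
    t2 <- compare_models_aic(df, list(a = "x", b = c("x", "noise")))
    t2$aic[t2$model == "b"] - t2$aic[t2$model == "a"]
  }, numeric(1))
  expect_gte(median(daic), 0.5)
  expect_lte(median(daic), 1.5)
})
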