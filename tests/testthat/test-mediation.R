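test_that("effect decomposition conserves acme + ade = total", {
  est <- mediation_estimate(acme = 0.2776, ade = -0.1483)
  expect_equal(est$total, 0.1293, tolerance = 1e-12)
  expect_equal(est$prop_mediated, 100 * 0.2776 / 0.1293, tolerance = 1e-12)

  # null second path: total reduces to the direct effect
  est0 <- mediation_estimate(acme = 0, ade = -0.3)
  expect_identical(est0$total, est0$ade)
  expect_equal(est0$prop_mediated, 0)

  # opposite-signed components can push the proportion outside [0, 100]
  expect_equal(proportion_mediated(-0.0132, 0.0427), -30.913, tolerance = 1e-3)
  expect_equal(proportion_mediated(1, 1), 100)
  expect_true(is.na(proportion_mediated(0.5, 0)))
})

test_that("product-of-coefficients equals difference-of-coefficients", {
  # exact OLS identity for a single mediator with identical covariates and
  # sample: a*b == c - c' where c is the exposure effect without the
  # mediator and c' with it
  withr::with_seed(200, {
    for (i in 1:25) {
      n <- 60
      x <- rnorm(n); z <- rnorm(n)
      m <- 0.5 * x + 0.3 * z + rnorm(n)
      y <- 0.4 * x + 0.7 * m - 0.2 * z + rnorm(n)
      xm <- cbind(`(Intercept)` = 1, x = x, z = z)
      xy <- cbind(`(Intercept)` = 1, x = x, m = m, z = z)
      fm <- fit_ols(xm, m)
      fy <- fit_ols(xy, y)
      est <- point_mediation(fm, fy, "x", "m")
      f_total <- fit_ols(xm, y)
      diff_coef <- f_total$coefficients$estimate[2] - fy$coefficients$estimate[2]
      expect_equal(est$acme, diff_coef, tolerance = 1e-10)
      # and hence total == marginal exposure effect
      expect_equal(est$total, f_total$coefficients$estimate[2], tolerance = 1e-10)
    }
  })
})

test_that("point_mediation validates term membership", {
  d <- random_design(30, 3, seed = 201)
  fit <- fit_ols(d$x, d$y)
  expect_error(point_mediation(fit, fit, "nope", "x1"),
               class = "eaamediate_spec_error")
})

test_that("bootstrap mediation is seed-deterministic and decomposition-exact", {
  co <- generate_cohort(sim_truth(n = 600, seed = 21))
  r1 <- run_mediation_analysis(co, "cs", "grim_eaa", "fg",
                               n_boot = 200, seed = 5)
  r2 <- run_mediation_analysis(co, "cs", "grim_eaa", "fg",
                               n_boot = 200, seed = 5)
  expect_identical(tidy(r1), tidy(r2))

  est <- r1$estimates
  expect_equal(est$estimate[est$effect == "total"],
               est$estimate[est$effect == "acme"] +
                 est$estimate[est$effect == "ade"],
               tolerance = 1e-12)

  # point estimates are invariant to the bootstrap seed; CIs vary
  r3 <- run_mediation_analysis(co, "cs", "grim_eaa", "fg",
                               n_boot = 200, seed = 99)
  expect_identical(r1$estimates$estimate, r3$estimates$estimate)
  expect_false(identical(r1$estimates$conf.low, r3$estimates$conf.low))

  expect_true(all(est$p.value >= 1 / r1$n_boot & est$p.value <= 1))
})

test_that("analysis n books outcome missingness and mediator outliers", {
  co <- generate_cohort(sim_truth(n = 500, seed = 22, lung_missing_rate = 0))
  n_complete <- nrow(co)
  base_outliers <- sum(!flag_extreme_outliers(co$grim_eaa), na.rm = TRUE)
  co$grim_eaa[17] <- co$grim_eaa[17] + 1000  # inject one extreme value
  r <- run_mediation_analysis(co, "cs", "grim_eaa", "fg",
                              n_boot = 100, seed = 1)
  expect_equal(r$n_outliers_removed, base_outliers + 1)
  expect_equal(r$n_analysis, n_complete - r$n_outliers_removed)

  # cessation analyses use former smokers only
  r_ysc <- run_mediation_analysis(co, "ysc", "grim_eaa", "fg",
                                  n_boot = 100, seed = 1)
  n_former <- sum(co$smoking_status == "former")
  expect_lte(r_ysc$n_analysis, n_former)
  expect_gte(r_ysc$n_analysis, n_former - r$n_outliers_removed)
})

test_that("low-noise status-only data recover the generator ACME", {
  # A mediator with exactly zero residual noise is an exact linear
  # combination of the outcome-model design columns, so the joint system is
  # unidentifiable in that limit. The well-posed deterministic limit keeps
  # an (arbitrarily small) mediator residual: the outcome model is then
  # noiseless given the realised mediator, its b-path and direct effect are
  # recovered exactly, and the ACME converges to the generator truth as the
  # mediator noise shrinks.
  base <- truth_status_only(n = 400, seed = 23, lung_missing_rate = 0)
  for (m in names(base$mediator_model)) {
    base$mediator_model[[m]]$sd <- 0
    base$mediator_model[[m]]$covariates[] <- 0
  }
  for (y in names(base$outcome_model)) {
    base$outcome_model[[y]]$sd <- 0
    base$outcome_model[[y]]$covariates[] <- 0
    keep <- base$outcome_model[[y]]$mediators[["grim_eaa"]]
    base$outcome_model[[y]]$mediators[] <- 0
    base$outcome_model[[y]]$mediators[["grim_eaa"]] <- keep
  }
  base$mediator_model$grim_eaa$sd <- 1e-6
  co <- generate_cohort(base)
  r <- run_mediation_analysis(co, "cs", "grim_eaa", "fev1",
                              n_boot = 100, seed = 1, standardize = FALSE)
  est <- r$estimates
  truth_val <- truth_acme(base, "cs", "grim_eaa", "fev1")
  expect_equal(est$estimate[est$effect == "acme"], truth_val,
               tolerance = 1e-4)
  expect_equal(est$estimate[est$effect == "ade"],
               base$outcome_model$fev1$exposure[["cs"]], tolerance = 1e-4)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  widths <- sapply(1:6, function(s) {
    co1 <- generate_cohort(truth_status_only(n = 400, seed = 300 + s))
    co2 <- generate_cohort(truth_status_only(n = 800, seed = 400 + s))
    w <- function(co) {
      est <- run_mediation_analysis(co, "cs", "grim_eaa", "fg",
                                    n_boot = 200, seed = s)$estimates
      est$conf.high[est$effect == "acme"] - est$conf.low[est$effect == "acme"]
    }
    w(co2) / w(co1)
  })
  expect_gt(median(widths), 0.55)
  expect_lt(median(widths), 0.85)
})

test_that("stratified resampling preserves group sizes and stays deterministic", {
  co <- generate_cohort(sim_truth(n = 500, seed = 24))
  r1 <- run_mediation_analysis(co, "cs", "grim_eaa", "fg", n_boot = 100,
                               seed = 2, stratified = TRUE)
  r2 <- run_mediation_analysis(co, "cs", "grim_eaa", "fg", n_boot = 100,
                               seed = 2, stratified = TRUE)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("tidy and glance expose the standard mediation columns", {
  co <- generate_cohort(sim_truth(n = 400, seed = 25))
  r <- run_mediation_analysis(co, "fs", "pheno_eaa", "hba1c",
                              n_boot = 100, seed = 1)
  td <- tidy(r)
  expect_setequal(td$effect, c("acme", "ade", "total"))
  expect_true(all(c("exposure", "mediator", "outcome", "estimate",
                    "conf.low", "conf.high", "p.value") %in% names(td)))
  g <- glance(r)
  expect_equal(g$total, g$acme + g$ade, tolerance = 1e-12)
  expect_equal(g$n_boot, 100)
})
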