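test_that("smoking status is dummy coded with non-smokers as reference", {
  co <- generate_cohort(sim_truth(n = 200, seed = 13))
  d <- build_design(co, model_spec("status", mediator = "grim_eaa"))
  sub <- co[d$rows, ]
  expect_identical(unname(d$x[, "fs"]), as.numeric(sub$smoking_status == "former"))
  expect_identical(unname(d$x[, "cs"]), as.numeric(sub$smoking_status == "current"))
  expect_identical(colnames(d$x)[1], "(Intercept)")
  # pack-year terms are zero for non-smokers
  d3 <- build_design(co, model_spec("packyears", mediator = "grim_eaa"))
  sub3 <- co[d3$rows, ]
  expect_true(all(d3$x[sub3$smoking_status == "non", c("fpy", "cpy")] == 0))
})

test_that("cessation models keep only former smokers with pack-years adjusted", {
  co <- generate_cohort(sim_truth(n = 500, seed = 14))
  spec <- model_spec("cessation", mediator = "grim_eaa")
  expect_true("pack_years" %in% spec$covariates)
  d <- build_design(co, spec)
  expect_equal(d$n, sum(co$smoking_status == "former"))
  expect_true("ysc" %in% colnames(d$x))
  expect_true("pack_years" %in% colnames(d$x))
})

test_that("listwise deletion drops outcome-missing rows only where required", {
  co <- generate_cohort(sim_truth(n = 300, seed = 15))
  n_lung <- sum(!is.na(co$fev1))
  y_spec <- model_spec("status", mediator = "grim_eaa", outcome = "fev1",
                       role = "outcome")
  dy <- build_design(co, y_spec)
  expect_equal(dy$n, n_lung)
  m_spec <- model_spec("status", mediator = "grim_eaa")
  dm <- build_design(co, m_spec)
  expect_equal(dm$n, nrow(co))  # mediator model keeps lung-missing rows
  dm_aligned <- build_design(co, m_spec, extra_required = "fev1")
  expect_equal(dm_aligned$n, n_lung)
})

test_that("fit_ols reproduces exact fits and the normal-equations oracle", {
  x <- cbind(`(Intercept)` = 1, x = as.numeric(1:5))
  fit <- fit_ols(x, 2 * (1:5) + 1)
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-12)

  d <- random_design(20, 3, seed = 99)
  fit <- fit_ols(d$x, d$y)
  beta_oracle <- solve(t(d$x) %*% d$x, t(d$x) %*% d$y)
  expect_equal(fit$coefficients$estimate, drop(beta_oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residual orthogonality to every design column
  expect_lt(max(abs(t(d$x) %*% fit$residuals)) / max(abs(d$y)), 1e-6)
})

test_that("classical standard errors match the lm() reference", {
  d <- random_design(40, 4, seed = 100)
  fit <- fit_ols(d$x, d$y)
  ref <- summary(lm(d$y ~ d$x[, -1]))$coefficients
  expect_equal(fit$coefficients$std.error, unname(ref[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$p.value, unname(ref[, "Pr(>|t|)"]),
               tolerance = 1e-10)
})

test_that("rank-deficient designs raise a collinearity error naming the column", {
  d <- random_design(20, 3, seed = 101)
  x <- cbind(d$x, dup = d$x[, "x1"])
  expect_error(fit_ols(x, d$y), regexp = "dup|x1",
               class = "eaamediate_collinearity_error")
})

test_that("adding a constant to the response shifts only the intercept", {
  d <- random_design(30, 4, seed = 102)
  f0 <- fit_ols(d$x, d$y)
  f1 <- fit_ols(d$x, d$y + 5)
  expect_equal(f1$coefficients$estimate[1], f0$coefficients$estimate[1] + 5,
               tolerance = 1e-10)
  expect_equal(f1$coefficients$estimate[-1], f0$coefficients$estimate[-1],
               tolerance = 1e-10)
})

test_that("Frisch-Waugh partialling-out reproduces the focal coefficient", {
  withr::with_seed(103, {
    for (i in 1:10) {
      n <- 50
      x <- cbind(`(Intercept)` = 1, f = rnorm(n), z1 = rnorm(n), z2 = rnorm(n))
      y <- rnorm(n)
      full <- fit_ols(x, y)
      zc <- x[, c("(Intercept)", "z1", "z2")]
      rf <- stats::lm.fit(zc, x[, "f"])$residuals
      ry <- stats::lm.fit(zc, y)$residuals
      partial <- sum(rf * ry) / sum(rf^2)
      expect_equal(full$coefficients$estimate[2], partial, tolerance = 1e-10)
    }
  })
})

test_that("age-residualised epigenetic age is uncorrelated with age", {
  withr::with_seed(104, {
    age <- runif(300, 30, 70)
    epi <- age + rnorm(300, 0, 4)
    eaa <- residualize_on_age(epi, age)
    expect_lt(abs(cor(eaa, age)), 1e-10)
  })
  age <- c(30, 40, 50, 60)
  expect_equal(residualize_on_age(age, age), rep(0, 4), tolerance = 1e-12)
  expect_equal(residualize_on_age(age + 7, age), rep(0, 4), tolerance = 1e-12)
  expect_error(residualize_on_age(c(1, 2, 3), rep(50, 3)),
               class = "eaamediate_degenerate_regressor")
})

test_that("VIF is 1 for orthogonal predictors and 1/(1-r^2) pairwise", {
  withr::with_seed(105, {
    # columns orthonormal to each other and to the intercept
    q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, 2:4]
    x <- cbind(a = q[, 1], b = q[, 2], c = q[, 3])
    v <- compute_vif(x)
    expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)
    expect_false(any(v$flagged))

    # two predictors with exact sample correlation 0.8
    e <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 2), 50, 2))))[, 2:3]
    x2 <- cbind(p = e[, 1], q = 0.8 * e[, 1] + 0.6 * e[, 2])
    v2 <- compute_vif(x2)
    expect_equal(v2$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-8)

    expect_error(compute_vif(cbind(a = e[, 1], b = 2 * e[, 1])),
                 class = "eaamediate_collinearity_error")
  })
})

test_that("VIF agrees with the car reference and stays finite on cohort designs", {
  co <- generate_cohort(sim_truth(n = 800, seed = 16))
  d <- build_design(co, model_spec("status", mediator = "grim_eaa"))
  v <- compute_vif(d$x)
  expect_true(all(is.finite(v$vif)))
  df <- as.data.frame(d$x[, -1])
  df$y <- d$y
  ref <- car::vif(lm(y ~ ., data = df))
  expect_equal(v$vif, unname(ref[v$term]), tolerance = 1e-6)
})
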