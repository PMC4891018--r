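test_that("baseline survivor matches closed forms and the published constant", {
  expect_equal(round(baseline_survivor(1.7376, 1.0769, 1), 4), 0.1632)
  expect_equal(baseline_survivor(2.3, 0.8, 0), 1)
  expect_equal(baseline_survivor(1, 1, 1), exp(-1))
  expect_error(baseline_survivor(1, 1, -1), class = "mrscore_validation_error")
  expect_error(baseline_survivor(-1, 1, 1), class = "mrscore_validation_error")
})

test_that("per-SD hazard ratios reproduce the published lysine and TG15 values", {
  expect_equal(round(hazard_ratio_per_sd(-0.020, 51.73), 2), 0.36)
  expect_equal(round(hazard_ratio_per_sd(-0.483, 2.88), 2), 0.25)
  expect_equal(hazard_ratio_per_sd(0, 17), 1)
  expect_error(hazard_ratio_per_sd(0.1, 0), class = "mrscore_validation_error")
})

test_that("the empty-model MLE recovers exponential data as shape 1", {
  d <- simulate_weibull_direct(2000, lambda = 1, gamma = 1, seed = 4)
  fit <- fit_weibull_ph(d)
  se_g <- fit$gamma * sqrt(fit$vcov["log_gamma", "log_gamma"])
  se_l <- fit$lambda * sqrt(fit$vcov["beta0", "beta0"])
  expect_lt(abs(fit$gamma - 1), 3 * se_g)
  expect_lt(abs(fit$lambda - 1), 3 * se_l)
})

test_that("a binary-covariate effect is recovered and matches the grid-search oracle", {
  withr::with_seed(8, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
  })
  d <- simulate_weibull_direct(n = 2000, lambda = 1.5, gamma = 1.2, beta = 0.7,
                               X = matrix(x, ncol = 1), censor_max = 3, seed = 1008)
  d$x <- x
  fit <- fit_weibull_ph(d, "x")
  se_b <- fit$wald$std.error[1]
  expect_lt(abs(fit$coefficients[["x"]] - 0.7), 3 * se_b)

  sub <- d[1:50, ]
  fit50 <- fit_weibull_ph(sub, "x")
  grid <- oracle_grid_mle(sub$time_years, sub$event, x = sub$x)
  expect_equal(fit50$lambda, grid$lambda, tolerance = 1e-4)
  expect_equal(fit50$gamma, grid$gamma, tolerance = 1e-4)
  expect_equal(unname(fit50$coefficients[["x"]]), grid$beta, tolerance = 1e-4)
  # and the likelihoods agree through the independent formula
  expect_equal(fit50$loglik,
               oracle_loglik(sub$time_years, sub$event, fit50$lambda, fit50$gamma,
                             fit50$coefficients, matrix(sub$x, ncol = 1)),
               tolerance = 1e-8)
})

test_that("the MLE agrees with survreg's transformed AFT estimates", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 500, seed = 12))
  mets <- attr(ch, "spec")$metabolite_names
  fit <- fit_weibull_ph(ch, mets)
  sr <- survival::survreg(
    survival::Surv(time_years, event) ~ valine + smc24_1 + lysine + tg15 + sdma,
    data = ch
  )
  expect_equal(fit$gamma, 1 / sr$scale, tolerance = 1e-5)
  expect_equal(fit$lambda, exp(-unname(coef(sr)[1])), tolerance = 1e-5)
  expect_equal(unname(fit$coefficients),
               unname(-coef(sr)[-1] / sr$scale), tolerance = 1e-5)
  expect_equal(fit$loglik, sr$loglik[2], tolerance = 1e-8)
  expect_equal(fit$aic, -2 * sr$loglik[2] + 2 * (length(mets) + 2))
})

test_that("rescaling time rescales the scale parameter and nothing else", {
  d <- simulate_weibull_direct(800, lambda = 1.7, gamma = 1.3, seed = 5)
  f1 <- fit_weibull_ph(d)
  d2 <- d
  d2$time_years <- d2$time_years * 3
  f2 <- fit_weibull_ph(d2)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-6)
  expect_equal(f2$lambda, f1$lambda / 3, tolerance = 1e-6)
})

test_that("centering shifts only the intercept", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 300, seed = 6))
  mets <- attr(ch, "spec")$metabolite_names
  f_raw <- fit_weibull_ph(ch, mets)
  f_cen <- fit_weibull_ph(ch, mets, center = TRUE)
  expect_equal(f_cen$coefficients, f_raw$coefficients, tolerance = 1e-7)
  expect_equal(f_cen$gamma, f_raw$gamma, tolerance = 1e-7)
  expect_equal(f_cen$loglik, f_raw$loglik, tolerance = 1e-9)
  xbar <- colMeans(ch[mets])
  # (lambda_c)^gamma = lambda^gamma * exp(xbar' beta)  =>  b0 shifts by -xbar' beta / gamma
  expect_equal(f_cen$beta0,
               f_raw$beta0 - sum(f_raw$coefficients * xbar) / f_raw$gamma,
               tolerance = 1e-6)
  expect_equal(unname(f_cen$centering), unname(xbar))
})

test_that("fits refuse degenerate inputs", {
  d <- tibble::tibble(time_years = c(1, 2, 3), event = c(0, 0, 0))
  expect_error(fit_weibull_ph(d), class = "mrscore_validation_error")
  d2 <- tibble::tibble(time_years = c(1, 2, 3), event = c(1, 0, 1),
                       x = c(1, NA, 2))
  expect_error(fit_weibull_ph(d2, "x"), class = "mrscore_validation_error")
  d3 <- tibble::tibble(time_years = c(-1, 2, 3), event = c(1, 0, 1))
  expect_error(fit_weibull_ph(d3), class = "mrscore_validation_error")
})

test_that("fit objects predict, tidy, and survive a JSON round trip", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 150, seed = 19))
  fit <- fit_weibull_ph(ch, c("sdma", "tg15"), center = TRUE)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  g <- glance(fit)
  expect_equal(g$AIC, -2 * g$logLik + 2 * 4)

  risk <- predict(fit, ch, t = 1, type = "risk")
  surv <- predict(fit, ch, t = 1, type = "survival")
  expect_equal(risk, 1 - surv)
  expect_true(all(risk > 0 & risk < 1))

  path <- withr::local_tempfile(fileext = ".json")
  weibull_fit_to_json(fit, path)
  back <- weibull_fit_from_json(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(predict(back, ch, type = "risk"), risk)
})

test_that("adding pure noise covariates tends to increase AIC", {
  deltas <- vapply(1:12, function(s) {
    ch <- generate_cohort(pdac_cohort_spec(n_patients = 200, seed = 100 + s,
                                           n_noise_covariates = 1))
    f0 <- fit_weibull_ph(ch, "sdma")
    f1 <- fit_weibull_ph(ch, c("sdma", "noise_1"))
    f1$aic - f0$aic
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("the log-log diagnostic is straight for Weibull data and bent for log-normal", {
  d <- simulate_weibull_direct(2000, lambda = 1.7376, gamma = 1.0769,
                               censor_max = 4, seed = 23)
  diag_w <- weibull_loglog_diagnostic(d)
  expect_gt(attr(diag_w, "r_squared"), 0.98)
  expect_lt(abs(attr(diag_w, "slope") - 1.0769), 0.1)

  dl <- withr::with_seed(23, {
    t0 <- exp(rnorm(2000, meanlog <- -0.5, 1.6))
    cmax <- runif(2000, 0, 4)
    tibble::tibble(time_years = pmin(t0, cmax), event = as.integer(t0 <= cmax))
  })
  diag_l <- weibull_loglog_diagnostic(dl)
  expect_lt(attr(diag_l, "r_squared"), attr(diag_w, "r_squared") - 0.01)

  single <- tibble::tibble(time_years = c(1, 2), event = c(1, 0))
  expect_error(weibull_loglog_diagnostic(single),
               class = "mrscore_validation_error")
})
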