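published_model <- function() {
  mrs_model(
    metabolites = c("valine", "smc24_1", "lysine", "tg15", "sdma"),
    means = c(249.84, 23.93, 200.53, 8.46, 0.76),
    betas = c(-0.005, 0.047, -0.020, -0.483, 1.314),
    lambda = 1.7376, gamma = 1.0769
  )
}

patient_at_means <- function() {
  tibble::tibble(valine = 249.84, smc24_1 = 23.93, lysine = 200.53,
                 tg15 = 8.46, sdma = 0.76)
}

test_that("the published formula evaluates as printed", {
  m <- published_model()
  expect_equal(round(baseline_survivor(m$lambda, m$gamma, m$t), 4), 0.1632)
  at_means <- compute_mrs(patient_at_means(), m)$mrs
  expect_equal(at_means, 1 - 0.1632, tolerance = 1e-4)
  one_sd_val <- patient_at_means()
  one_sd_val$valine <- 249.84 + 98.57
  expect_equal(compute_mrs(one_sd_val, m)$mrs, 0.6696, tolerance = 1e-4)
  one_sd_sdma <- patient_at_means()
  one_sd_sdma$sdma <- 0.76 + 0.62
  expect_equal(compute_mrs(one_sd_sdma, m)$mrs, 0.9833, tolerance = 1e-4)
})

test_that("an exponential baseline with rate log 2 halves survival by one year", {
  m <- mrs_model("x", means = 0, betas = 1, lambda = log(2), gamma = 1)
  expect_equal(baseline_survivor(m$lambda, m$gamma, 1), 0.5)
  expect_equal(compute_mrs(tibble::tibble(x = 0), m)$mrs, 0.5)
})

test_that("the score is strictly monotone with limits 0 and 1", {
  m <- published_model()
  base <- patient_at_means()
  sds <- c(98.57, 20.67, 51.73, 2.88, 0.62)
  for (i in seq_along(m$metabolites)) {
    met <- m$metabolites[i]
    grid <- base[rep(1, 200), ]
    # +-2 SD: the physiologic range; further out the strongest weight
    # (TG15) saturates the score to exactly 1.0 in double precision even
    # though it is mathematically < 1
    grid[[met]] <- seq(m$means[i] - 2 * sds[i], m$means[i] + 2 * sds[i],
                       length.out = 200)
    s <- compute_mrs(grid, m)$mrs
    expect_true(all(s > 0 & s < 1))
    d <- diff(s)
    if (m$betas[i] > 0) expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
  # limits via extreme SDMA (largest positive weight)
  lo <- base; lo$sdma <- -50
  hi <- base; hi$sdma <- 50
  expect_lt(compute_mrs(lo, m)$mrs, 1e-12)
  expect_gt(compute_mrs(hi, m)$mrs, 1 - 1e-12)
})

test_that("build_mrs wires the empty and multivariable fits together", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 300, seed = 44))
  empty <- fit_weibull_ph(ch)
  multi <- fit_weibull_ph(ch, c("sdma", "tg15"), center = TRUE)
  m <- build_mrs(empty, multi)
  expect_equal(m$lambda, empty$lambda)
  expect_equal(m$gamma, empty$gamma)
  expect_equal(m$betas, multi$coefficients)
  expect_equal(m$means, multi$centering)

  # scoring equals the Weibull module's survivor arithmetic to machine precision
  scored <- compute_mrs(ch, m)
  lp <- as.matrix(sweep(ch[m$metabolites], 2, m$means)) %*% m$betas
  expect_equal(scored$mrs,
               drop(1 - baseline_survivor(empty$lambda, empty$gamma, 1)^exp(lp)),
               tolerance = 1e-15)

  expect_error(build_mrs(multi, multi), class = "mrscore_validation_error")
  expect_error(build_mrs(empty, multi, sample_means = c(wrong = 1)),
               class = "mrscore_validation_error")
  expect_error(build_mrs(empty, fit_weibull_ph(ch, "sdma")),
               class = "mrscore_validation_error")
})

test_that("scoring refuses missing metabolites rather than imputing", {
  m <- published_model()
  p <- patient_at_means()
  p$sdma <- NA_real_
  expect_error(compute_mrs(p, m), class = "mrscore_validation_error")
  expect_error(compute_mrs(p[, -1], m), class = "mrscore_validation_error")
})

test_that("models survive a JSON round trip bit-identically", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 100, seed = 55))
  m <- published_model()
  path <- withr::local_tempfile(fileext = ".json")
  mrs_to_json(m, path)
  back <- mrs_from_json(path)
  expect_identical(compute_mrs(ch, back)$mrs, compute_mrs(ch, m)$mrs)
})

test_that("bootstrap weights are seeded, validated, and centred on the fit", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 150, seed = 66))
  mets <- c("sdma", "tg15")
  expect_error(bootstrap_weights(ch, mets, n_boot = 0),
               class = "mrscore_validation_error")
  b1 <- bootstrap_weights(ch, mets, n_boot = 150, seed = 4)
  b2 <- bootstrap_weights(ch, mets, n_boot = 150, seed = 4)
  expect_identical(b1$ci, b2$ci)
  fit <- fit_weibull_ph(ch, mets)
  ok <- b1$ci$conf_low < fit$coefficients[b1$ci$term] &
    fit$coefficients[b1$ci$term] < b1$ci$conf_high
  expect_true(all(ok))
})

test_that("a cohort that cannot support refits aborts the bootstrap loudly", {
  d <- tibble::tibble(
    time_years = c(0.1, 1, 2, 3, 4, 5),
    event = c(1, 0, 0, 0, 0, 0), # a single event: ~37% of resamples lose it
    x = rnorm(6)
  )
  expect_error(
    suppressWarnings(bootstrap_weights(d, "x", n_boot = 100, seed = 1)),
    class = "mrscore_bootstrap_error"
  )
})

test_that("per-SD hazard-ratio intervals inherit the weight distribution's asymmetry", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 40, seed = 77))
  boot <- bootstrap_weights(ch, c("sdma", "tg15"), n_boot = 400, seed = 9)
  hr <- bootstrap_hr_per_sd(boot, c(sdma = 0.62))
  # small-sample log-scale weights: the HR interval stretches to the right
  expect_gt(hr$conf_high - hr$hr, hr$hr - hr$conf_low)
  expect_true(hr$conf_low < hr$hr & hr$hr < hr$conf_high)
})

test_that("tidy and glance expose the score's parts", {
  m <- published_model()
  td <- tidy(m)
  expect_equal(td$estimate, unname(m$betas))
  g <- glance(m)
  expect_equal(g$baseline_survivor, baseline_survivor(1.7376, 1.0769, 1))
})
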