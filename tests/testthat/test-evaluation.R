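test_that("perfect risk ordering gives concordance exactly 1", {
  withr::with_seed(1, {
    n <- 20
    t0 <- sort(runif(n, 0.1, 3))
    d <- tibble::tibble(time_years = t0, event = 1L)
    risk <- rev(seq_len(n)) / n # earliest death = highest risk
  })
  res <- cstat_censored(d, risk, n_boot = 0)
  expect_identical(res$c_statistic, 1)
  expect_equal(res$n_pairs, choose(20, 2))
})

test_that("a hand-built four-patient example is counted pair by pair", {
  d <- tibble::tibble(time_years = c(1, 2, 3, 4), event = 1L)
  risk <- c(0.9, 0.1, 0.8, 0.2)
  # pairs (1,2) (1,3) (1,4) (3,4) concordant; (2,3) (2,4) discordant
  oracle <- oracle_concordance(d$time_years, d$event, risk)
  expect_equal(oracle$c, 4 / 6)
  res <- cstat_censored(d, risk, n_boot = 0)
  expect_equal(res$c_statistic, oracle$c)
  expect_equal(res$n_pairs, oracle$n_pairs)
})

test_that("concordance equals exhaustive pair enumeration, censored or not", {
  withr::with_seed(5, {
    n <- 120
    risk <- runif(n)
    t0 <- rexp(n, exp(2 * risk))
    # uncensored
    d1 <- tibble::tibble(time_years = t0, event = 1L)
    # censored
    cmax <- runif(n, 0, quantile(t0, 0.7))
    d2 <- tibble::tibble(time_years = pmin(t0, cmax),
                         event = as.integer(t0 <= cmax))
  })
  for (d in list(d1, d2)) {
    oracle <- oracle_concordance(d$time_years, d$event, risk)
    res <- cstat_censored(d, risk, n_boot = 0)
    expect_equal(res$c_statistic, oracle$c, tolerance = 1e-12)
    expect_equal(res$n_pairs, oracle$n_pairs)
  }
})

test_that("an uninformative predictor sits at one half", {
  withr::with_seed(7, {
    n <- 2000
    d <- tibble::tibble(time_years = rexp(n, 1), event = 1L)
    risk <- runif(n)
  })
  res <- cstat_censored(d, risk, n_boot = 0)
  expect_lt(abs(res$c_statistic - 0.5), 0.03)
})

test_that("concordance errors when no pair is usable", {
  d <- tibble::tibble(time_years = c(1, 2, 3), event = 0L)
  expect_error(cstat_censored(d, c(0.1, 0.2, 0.3), n_boot = 0),
               class = "mrscore_validation_error")
})

test_that("comparing a predictor with itself gives zero difference, p near 1", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 150, seed = 31))
  res <- compare_cstats(ch, ch$true_lp, ch$true_lp, n_boot = 200, seed = 2)
  expect_equal(res$difference, 0)
  expect_gt(res$p_value, 0.9)
})

test_that("the true linear predictor beats pure noise decisively", {
  hits <- vapply(1:10, function(r) {
    ch <- generate_cohort(pdac_cohort_spec(n_patients = 500, seed = 800 + r))
    noise <- withr::with_seed(900 + r, runif(nrow(ch)))
    res <- compare_cstats(ch, ch$true_lp, noise, n_boot = 300, seed = r)
    res$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("small heavily censored cohorts give wide intervals without crashing", {
  withr::with_seed(41, {
    d <- tibble::tibble(
      time_years = runif(10, 0.1, 2),
      event = c(1L, 1L, rep(0L, 8)),
      risk = runif(10)
    )
  })
  res <- compare_cstats(d, d$risk, rev(d$risk), n_boot = 200, seed = 3)
  expect_true(is.finite(res$p_value))
  expect_gt(res$conf_high - res$conf_low, 0)
})

test_that("Kaplan-Meier reduces to the empirical survivor function without censoring", {
  d <- tibble::tibble(time_years = 1:10, event = 1L)
  km <- kaplan_meier(d)
  expect_equal(km$estimate, 1 - (1:10) / 10)
  expect_equal(km$n_risk, 10:1)
})

test_that("Kaplan-Meier matches the hand-worked product over risk sets", {
  # times 1 (event), 2 (censored), 3 (event):
  # S(1) = 2/3; S(3) = 2/3 * (1 - 1/1) = 0
  d <- tibble::tibble(time_years = c(1, 2, 3), event = c(1L, 0L, 1L))
  km <- kaplan_meier(d)
  expect_equal(km$estimate[km$time == 1], 2 / 3)
  expect_equal(km$estimate[km$time == 3], 0)
  # all censored
  d2 <- tibble::tibble(time_years = c(1, 2), event = 0L)
  expect_true(all(kaplan_meier(d2)$estimate == 1))
})

test_that("stratified Kaplan-Meier carries the strata labels through", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 120, seed = 51))
  ch$grp <- rep(c("a", "b"), 60)
  km <- kaplan_meier(ch, by = "grp")
  expect_setequal(unique(km$strata), c("a", "b"))
})

test_that("mortality rates follow person-time arithmetic and truncation", {
  d <- tibble::tibble(time_years = c(1, 3), event = c(1L, 1L))
  expect_equal(mortality_rate(d)$rate_per_100py, 100 * 2 / 4)
  # event at 2y is beyond a 1-year horizon: contributes 1 py, no event
  d2 <- tibble::tibble(time_years = 2, event = 1L)
  r2 <- mortality_rate(d2, horizon = 1)
  expect_equal(r2$events, 0L)
  expect_equal(r2$person_years, 1)
  # invariant to patient order
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 80, seed = 61))
  expect_equal(mortality_rate(ch, horizon = 1),
               mortality_rate(ch[sample(80), ], horizon = 1))
  expect_error(mortality_rate(d, horizon = -1), class = "mrscore_validation_error")
})

test_that("the one-year rate matches the closed-form Weibull person-time integral", {
  spec <- pdac_cohort_spec(n_patients = 5000, seed = 71, betas = rep(0, 5),
                           censor_time_max = 1e6)
  ch <- generate_cohort(spec)
  got <- mortality_rate(ch, horizon = 1)$rate_per_100py
  p_death <- 1 - baseline_survivor(spec$lambda0, spec$gamma0, 1)
  e_py <- stats::integrate(function(t) baseline_survivor(spec$lambda0, spec$gamma0, t),
                           0, 1)$value
  expect_equal(got, 100 * p_death / e_py, tolerance = 0.03)
})

test_that("clinical associations pick the right test per variable type", {
  ch <- inject_clinical(
    generate_cohort(pdac_cohort_spec(n_patients = 400, seed = 81)),
    c(sdma = 0.4), seed = 2
  )
  ch$binary <- rep(c("x", "y"), 200)
  ch$flat <- 1
  tab <- clinical_associations(ch, c("ldh", "binary", "smoking", "flat"),
                               c("sdma", "valine"))
  expect_equal(tab$method[tab$clinical == "ldh"], rep("spearman", 2))
  expect_equal(tab$method[tab$clinical == "binary"], rep("mann-whitney", 2))
  expect_equal(tab$method[tab$clinical == "smoking"], rep("kruskal-wallis", 2))
  expect_true(all(is.na(tab$p_value[tab$clinical == "flat"])))
  expect_true(all(grepl("constant", tab$note[tab$clinical == "flat"])))
  est <- tab$estimate[tab$clinical == "ldh" & tab$metabolite == "sdma"]
  expect_lt(abs(est - 0.4), 0.12)
  tab_bh <- clinical_associations(ch, "ldh", c("sdma", "valine"), adjust = "BH")
  expect_true("p_adjusted" %in% names(tab_bh))
})

test_that("association p-values are calibrated under the null", {
  withr::with_seed(91, {
    pvals <- vapply(1:150, function(r) {
      d <- tibble::tibble(group = rep(c("a", "b"), 20), met = rnorm(40))
      clinical_associations(d, "group", "met")$p_value
    }, numeric(1))
  })
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.12)
})
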