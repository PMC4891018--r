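make_signal_cohort <- function(n = 200, seed = 1, strong = TRUE) {
  withr::with_seed(seed, {
    x_sig <- rbinom(n, 1, 0.5)
    noise <- matrix(rnorm(n * 9), n, 9,
                    dimnames = list(NULL, paste0("noise_", 1:9)))
    eta <- if (strong) 1.5 * x_sig else rep(0, n)
    t0 <- (1 / 1.5) * (-log(runif(n)) * exp(-eta))^(1 / 1.1)
    cmax <- runif(n, 0, 1.5)
    d <- tibble::tibble(time_years = pmin(t0, cmax),
                        event = as.integer(t0 <= cmax), marker = x_sig)
    dplyr::bind_cols(d, tibble::as_tibble(noise))
  })
}

test_that("the missingness screen applies the strictly-greater-than rule", {
  d <- tibble::tibble(
    a = c(rep(NA, 6), rnorm(14)),  # 30% -> excluded
    b = c(rep(NA, 5), rnorm(15)),  # exactly 25% -> retained
    c = rnorm(20)                  # complete -> retained
  )
  sc <- screen_covariates(d, c("a", "b", "c"), threshold = 0.25)
  expect_equal(sc$retained, c(FALSE, TRUE, TRUE))
  expect_equal(sc$missing_rate, c(0.30, 0.25, 0))
})

test_that("a learnable signal beats chance out of bag; pure noise does not", {
  cfg <- forest_config(n_trees = 500, seed = 7)
  sig <- grow_forest(make_signal_cohort(200, seed = 11, strong = TRUE),
                     c("marker", paste0("noise_", 1:9)), cfg)
  expect_lt(sig$oob_error, 0.45)
  nul <- grow_forest(make_signal_cohort(200, seed = 12, strong = FALSE),
                     c("marker", paste0("noise_", 1:9)), cfg)
  expect_gt(nul$oob_error, 0.42)
  expect_lt(nul$oob_error, 0.58)
})

test_that("forests are deterministic given the config seed", {
  d <- make_signal_cohort(150, seed = 21)
  cfg <- forest_config(n_trees = 300, seed = 99)
  f1 <- grow_forest(d, c("marker", paste0("noise_", 1:9)), cfg)
  f2 <- grow_forest(d, c("marker", paste0("noise_", 1:9)), cfg)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(f1$ranger$variable.importance, f2$ranger$variable.importance)
})

test_that("permutation importance ranks the true signal first with relative importance 1", {
  d <- make_signal_cohort(250, seed = 31, strong = TRUE)
  cfg <- forest_config(n_trees = 500, seed = 5)
  vimp <- permutation_importance(grow_forest(d, c("marker", paste0("noise_", 1:9)), cfg))
  expect_identical(vimp$covariate[1], "marker")
  expect_identical(vimp$relative_importance[1], 1)
  expect_identical(vimp$rank, seq_len(10L))
  # a constant covariate is never split on and gets ~zero importance
  d$flat <- 1
  vimp2 <- permutation_importance(grow_forest(d, c("marker", "flat",
                                                   paste0("noise_", 1:9)), cfg))
  expect_lt(abs(vimp2$score[vimp2$covariate == "flat"]), 1e-6)
})

test_that("the importance screen honours at-least vs strictly-greater wording", {
  vimp <- tibble::tibble(
    covariate = c("a", "b", "c"),
    score = c(10, 5, 1.9),
    relative_importance = c(1, 0.5, 0.19),
    rank = 1:3
  )
  expect_identical(apply_importance_screen(vimp, 0.20), c("a", "b"))
  vimp2 <- tibble::tibble(
    covariate = c("a", "b", "c", "d"),
    score = c(1, 0.35, 0.34, 0.33),
    relative_importance = c(1, 0.35, 0.34, 0.33),
    rank = 1:4
  )
  expect_identical(apply_importance_screen(vimp2, 0.34, strictly_greater = TRUE),
                   c("a", "b"))
  vimp3 <- dplyr::mutate(vimp, relative_importance = 0)
  expect_length(apply_importance_screen(vimp3, 0.20), 0)
})

test_that("imputation is the identity on complete data", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 100, seed = 61))
  mets <- attr(ch, "spec")$metabolite_names
  out <- impute_missing_in_forest(ch, mets, forest_config(n_trees = 100, seed = 1))
  expect_identical(out, ch)
})

test_that("MCAR holes are refilled near the true column mean, observed values untouched", {
  spec <- pdac_cohort_spec(n_patients = 250, seed = 71,
                           missing_rates = c(0.10, 0, 0, 0, 0))
  ch <- generate_cohort(spec)
  mets <- spec$metabolite_names
  holes <- which(is.na(ch$valine))
  out <- impute_missing_in_forest(ch, mets, forest_config(n_trees = 150, seed = 2))
  expect_false(anyNA(out[mets]))
  expect_identical(out$valine[-holes], ch$valine[-holes])
  se <- 98.57 / sqrt(length(holes))
  expect_lt(abs(mean(out$valine[holes]) - 249.84), 3 * se)
})

test_that("imputation exploits a perfectly rank-correlated companion covariate", {
  withr::with_seed(81, {
    n <- 250
    z <- rnorm(n)
    # survival driven by z, so the forest stratifies on its proxy
    t0 <- (1 / 1.5) * (-log(runif(n)) * exp(-1.2 * z))^(1 / 1.1)
    cmax <- runif(n, 0, 1.5)
    d <- tibble::tibble(
      time_years = pmin(t0, cmax), event = as.integer(t0 <= cmax),
      proxy = z, target = z + 5
    )
    truth <- d$target
    holes <- sample.int(n, 40)
    d$target[holes] <- NA
    out <- impute_missing_in_forest(d, c("proxy", "target"),
                                    forest_config(n_trees = 200, seed = 3))
    rmse_forest <- sqrt(mean((out$target[holes] - truth[holes])^2))
    marginal <- withr::with_seed(4, sample(truth[-holes], length(holes), replace = TRUE))
    rmse_marginal <- sqrt(mean((marginal - truth[holes])^2))
    expect_lt(rmse_forest, rmse_marginal)
  })
})

test_that("imputation refuses unimputable or unscreened covariates", {
  ch <- generate_cohort(pdac_cohort_spec(n_patients = 50, seed = 91))
  ch$gone <- NA_real_
  expect_error(
    impute_missing_in_forest(ch, c("valine", "gone"), forest_config(n_trees = 50)),
    class = "mrscore_validation_error"
  )
  ch2 <- generate_cohort(pdac_cohort_spec(n_patients = 100, seed = 92,
                                          missing_rates = c(0.4, 0, 0, 0, 0)))
  expect_error(
    impute_missing_in_forest(ch2, attr(ch2, "spec")$metabolite_names,
                             forest_config(n_trees = 50)),
    class = "mrscore_validation_error"
  )
})

test_that("the log-rank split statistic matches survdiff", {
  # hand-built 8-patient node
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- c(0, 0, 0, 0, 1, 1, 1, 1)
  ours <- logrank_split_statistic(time, event, group)
  sd8 <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(ours, sd8$chisq, tolerance = 1e-10)
  # and on messier simulated data with ties
  withr::with_seed(13, {
    t2 <- sample(1:20, 60, replace = TRUE)
    e2 <- rbinom(60, 1, 0.7)
    g2 <- rbinom(60, 1, 0.4)
  })
  expect_equal(logrank_split_statistic(t2, e2, g2),
               survival::survdiff(survival::Surv(t2, e2) ~ g2)$chisq,
               tolerance = 1e-10)
  expect_true(is.na(logrank_split_statistic(t2, e2, rep(1, 60))))
})
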