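#' Generate a synthetic right-censored cohort
#'
#' Draws metabolite concentrations independently from zero-truncated Normal
#' marginals, then generates event times by inverse-transform sampling from
#' the Weibull proportional-hazards model
#' `S(t | x) = exp{-(lambda0 * t)^gamma0 * exp(x_c' beta)}`, where `x_c` is
#' the covariate vector centered at the spec means:
#' `t = (1 / lambda0) * (-log(U) * exp(-x_c' beta))^(1 / gamma0)`.
#' Administrative censoring times are uniform on (0, `censor_time_max`];
#' the observed time is the minimum of the two and the event flag marks
#' whether death came first.  MCAR missingness is punched into the metabolite
#' columns after time generation, so the ground truth is unaffected.
#'
#' The returned tibble keeps the generator's ground truth in the
#' `true_lp` (centered linear predictor) and `true_event_time` columns;
#' downstream model fits never see these unless explicitly asked to.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `mrs_cohort` with columns `patient_id`,
#'   `time_years`, `event`, one column per metabolite (and `noise_*`
#'   columns when requested), plus `true_lp` and `true_event_time`.
#'   The spec is attached as attribute `"spec"`.
#' @examples
#' cohort <- generate_cohort(pdac_cohort_spec(n_patients = 50, seed = 7))
#' mean(cohort$event)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_invalid("`spec` must be a `cohort_spec` object.")
  }
  n <- spec$n_patients
  p <- length(spec$metabolite_names)
  withr::with_seed(spec$seed, {
    X <- vapply(
      seq_len(p),
      function(i) rtruncnorm(n, spec$means[i], spec$sds[i]),
      numeric(n)
    )
    colnames(X) <- spec$metabolite_names
    lp <- drop(sweep(X, 2, spec$means) %*% spec$betas)
    u <- runif(n)
    true_time <- (1 / spec$lambda0) *
      (-log(u) * exp(-lp))^(1 / spec$gamma0)
    cens <- runif(n, 0, spec$censor_time_max)
    time_obs <- pmin(true_time, cens)
    event <- as.integer(true_time <= cens)
    noise <- NULL
    if (spec$n_noise_covariates > 0) {
      noise <- matrix(rnorm(n * spec$n_noise_covariates),
                      nrow = n,
                      dimnames = list(NULL, paste0("noise_", seq_len(spec$n_noise_covariates))))
    }
    # MCAR holes, metabolites only
    for (i in seq_len(p)) {
      if (spec$missing_rates[i] > 0) {
        holes <- runif(n) < spec$missing_rates[i]
        X[holes, i] <- NA_real_
      }
    }
    out <- tibble(
      patient_id = seq_len(n),
      time_years = time_obs,
      event = event
    )
    out <- dplyr::bind_cols(out, as_tibble(X))
    if (!is.null(noise)) out <- dplyr::bind_cols(out, as_tibble(noise))
    out$true_lp <- lp
    out$true_event_time <- true_time
    attr(out, "spec") <- spec
    class(out) <- c("mrs_cohort", class(out))
    out
  })
}

#' Add correlated clinical covariates to a synthetic cohort
#'
#' Appends a lactate-dehydrogenase (LDH) column constructed through a
#' Gaussian copula on the metabolite ranks, so that the realised Spearman
#' correlation with each named metabolite approaches its target as the cohort
#' grows, together with age (Normal around 66 y), smoking habit and alcohol
#' consumption categories drawn from the frequencies typical of a pancreatic
#' cancer clinic population.  Clinical columns never enter event-time
#' generation; they are confounder stand-ins for adjustment analyses.
#'
#' @param cohort An `mrs_cohort` from [generate_cohort()].
#' @param target_correlations Named numeric vector: target Spearman rho
#'   between LDH and each named metabolite (|rho| < 1, and jointly feasible:
#'   the implied normal-score weights must leave positive residual variance).
#' @param seed Integer seed.
#' @return The cohort tibble with `ldh`, `age`, `smoking`, `alcohol` added.
#' @export
inject_clinical <- function(cohort, target_correlations = numeric(0), seed = 1L) {
  if (!is.data.frame(cohort)) stop_invalid("`cohort` must be a data frame.")
  bad <- setdiff(names(target_correlations), names(cohort))
  if (length(bad)) {
    stop_invalid(paste0("Metabolite(s) not in cohort: ", paste(bad, collapse = ", ")))
  }
  if (any(abs(target_correlations) >= 1)) {
    stop_invalid("All target Spearman correlations must satisfy |rho| < 1.")
  }
  n <- nrow(cohort)
  withr::with_seed(as.integer(seed), {
    # Spearman target -> Pearson correlation of latent normal scores
    r <- 2 * sin(pi * target_correlations / 6)
    if (sum(r^2) >= 1) {
      stop_invalid("Target correlations are jointly infeasible (normal-score weights exceed unit variance).")
    }
    z <- rnorm(n) * sqrt(1 - sum(r^2))
    for (j in seq_along(r)) {
      x <- cohort[[names(r)[j]]]
      zx <- qnorm((rank(x, na.last = "keep") - 0.5) / sum(!is.na(x)))
      zx[is.na(zx)] <- rnorm(sum(is.na(zx)))
      z <- z + r[j] * zx
    }
    # LDH marginal: log-normal around the clinic median of ~348 UI/l
    cohort$ldh <- stats::qlnorm(pnorm(z), meanlog = log(348), sdlog = 0.30)
    cohort$age <- round(rnorm(n, mean = 66, sd = 14.8))
    cohort$smoking <- sample(c("no", "yes", "ex"), n,
                             replace = TRUE, prob = c(0.519, 0.222, 0.259))
    cohort$alcohol <- sample(
      c("none", "occasional", "moderate", "heavy"), n,
      replace = TRUE, prob = c(0.308, 0.385, 0.192, 0.115)
    )
  })
  cohort
}

#' Read and write cohort tables as CSV
#'
#' Plain UTF-8 CSV with a header row; missing values are empty cells.
#'
#' @param data Cohort data frame.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  as_tibble(read.csv(path, na.strings = "", fileEncoding = "UTF-8"))
}
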