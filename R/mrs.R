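#' Construct a metabolite risk-score model
#'
#' The score is the predicted probability of death within the horizon `t`
#' (default one year) under a Weibull proportional-hazards model:
#' `MRS = 1 - S0(t) ^ exp(sum_i beta_i (X_i - Xbar_i))`, with
#' `S0(t) = exp{-(lambda t)^gamma}` taken from the empty (covariate-free)
#' Weibull fit and the weights `beta_i` from the multivariable fit, each
#' metabolite centered at its sample mean.  The score is strictly inside
#' (0, 1) and increases in every metabolite with a positive coefficient.
#'
#' `mrs_model()` assembles a model directly from numbers (e.g. published
#' coefficients); `build_mrs()` assembles it from two fitted models.
#'
#' @param metabolites Character vector of metabolite names.
#' @param means Centering constants (sample means, umol/L).
#' @param betas Per-umol/L coefficients (score weights).
#' @param lambda,gamma Baseline Weibull scale and shape.
#' @param t Prediction horizon in years (default 1).
#' @param bootstrap Optional [bootstrap_weights()] result carrying the
#'   weight stability CIs.
#' @return An object of class `mrs_model`.
#' @examples
#' m <- mrs_model(
#'   metabolites = c("valine", "smc24_1", "lysine", "tg15", "sdma"),
#'   means = c(249.84, 23.93, 200.53, 8.46, 0.76),
#'   betas = c(-0.005, 0.047, -0.020, -0.483, 1.314),
#'   lambda = 1.7376, gamma = 1.0769
#' )
#' m
#' @export
mrs_model <- function(metabolites, means, betas, lambda, gamma, t = 1,
                      bootstrap = NULL) {
  if (length(metabolites) != length(means) || length(means) != length(betas)) {
    stop_invalid("`metabolites`, `means` and `betas` must have equal length.")
  }
  if (lambda <= 0 || gamma <= 0) stop_invalid("`lambda` and `gamma` must be positive.")
  if (t <= 0) stop_invalid("Horizon `t` must be positive.")
  structure(
    list(
      metabolites = as.character(metabolites),
      means = setNames(as.numeric(means), metabolites),
      betas = setNames(as.numeric(betas), metabolites),
      lambda = lambda, gamma = gamma, t = t,
      boot_ci = if (is.null(bootstrap)) NULL else bootstrap$ci,
      n_boot = if (is.null(bootstrap)) NA_integer_ else bootstrap$n_boot
    ),
    class = "mrs_model"
  )
}

#' @rdname mrs_model
#' @param empty_fit `weibull_ph_fit` without covariates; supplies
#'   `(lambda, gamma)`.
#' @param multivariable_fit `weibull_ph_fit` on the score metabolites;
#'   supplies the weights.
#' @param sample_means Named centering constants; defaults to the
#'   multivariable fit's stored centering constants (fit with
#'   `center = TRUE`).
#' @export
build_mrs <- function(empty_fit, multivariable_fit, sample_means = NULL,
                      t = 1, bootstrap = NULL) {
  if (!inherits(empty_fit, "weibull_ph_fit") ||
      !inherits(multivariable_fit, "weibull_ph_fit")) {
    stop_invalid("Both fits must be `weibull_ph_fit` objects.")
  }
  if (length(empty_fit$coefficients)) {
    stop_invalid("`empty_fit` must be the covariate-free Weibull model.")
  }
  mets <- names(multivariable_fit$coefficients)
  if (!length(mets)) stop_invalid("`multivariable_fit` has no covariates.")
  if (is.null(sample_means)) sample_means <- multivariable_fit$centering
  if (is.null(sample_means)) {
    stop_invalid("Supply `sample_means`, or fit the multivariable model with `center = TRUE`.")
  }
  if (!setequal(names(sample_means), mets)) {
    stop_invalid("Names of `sample_means` must match the multivariable fit's covariates.")
  }
  mrs_model(
    metabolites = mets,
    means = sample_means[mets],
    betas = multivariable_fit$coefficients[mets],
    lambda = empty_fit$lambda, gamma = empty_fit$gamma,
    t = t, bootstrap = bootstrap
  )
}

#' Score patients with a metabolite risk-score model
#'
#' Appends an `mrs` column with the predicted within-horizon mortality
#' probability.  Every model metabolite must be present, finite and
#' non-missing: scoring never imputes silently.
#'
#' @param data Patient data frame.
#' @param model An [mrs_model()].
#' @return `data` with an `mrs` column, values strictly in (0, 1).
#' @export
compute_mrs <- function(data, model) {
  if (!inherits(model, "mrs_model")) stop_invalid("`model` must be an `mrs_model`.")
  check_covariates_present(data, model$metabolites)
  X <- as.matrix(data[model$metabolites])
  if (anyNA(X) || any(!is.finite(X))) {
    stop_invalid("Missing or non-finite metabolite values; scoring does not impute.")
  }
  lp <- drop(sweep(X, 2, model$means[model$metabolites]) %*%
               model$betas[model$metabolites])
  s0 <- baseline_survivor(model$lambda, model$gamma, model$t)
  data$mrs <- 1 - s0^exp(lp)
  data
}

#' Bootstrap stability of score weights
#'
#' With-replacement patient-level resampling: at each iteration the
#' multivariable Weibull model is refitted on the resample and its
#' coefficients stored; resamples with no events or a non-converged fit are
#' redrawn (the count is reported).  Weight CIs are the empirical 2.5th and
#' 97.5th percentiles.  Seeded and deterministic.
#'
#' @param data Cohort data frame (complete in `metabolites`).
#' @param metabolites Score metabolites.
#' @param n_boot Number of bootstrap resamples (the published analysis used
#'   10,000; at least 100).
#' @param seed Integer seed.
#' @param time_col,event_col Outcome columns.
#' @param max_failure_frac Abort when more than this fraction of draws has
#'   to be redrawn (default 0.2).
#' @return A list of class `mrs_bootstrap`: `draws` (tibble, one row per
#'   resample), `ci` (term, conf_low, conf_high), `n_boot`, `n_redrawn`.
#' @export
bootstrap_weights <- function(data, metabolites, n_boot = 10000, seed = 1L,
                              time_col = "time_years", event_col = "event",
                              max_failure_frac = 0.2) {
  if (n_boot < 100) stop_invalid("`n_boot` must be at least 100.")
  check_outcome(data, time_col, event_col)
  check_covariates_present(data, metabolites)
  if (anyNA(data[metabolites])) stop_invalid("Missing metabolite values; impute or drop first.")
  n <- nrow(data)
  p <- length(metabolites)
  draws <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, metabolites))
  n_redrawn <- 0L
  max_redraws <- ceiling(max_failure_frac * n_boot)
  withr::with_seed(as.integer(seed), {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- data[idx, , drop = FALSE]
      fit <- NULL
      if (sum(boot[[event_col]]) >= 1) {
        fit <- tryCatch(
          suppressWarnings(fit_weibull_ph(boot, metabolites, time_col, event_col)),
          error = function(e) NULL
        )
      }
      if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraws) {
          abort(
            sprintf(
              "More than %.0f%% of bootstrap resamples failed to fit (%d failures after %d successes); the model is too unstable to bootstrap.",
              100 * max_failure_frac, n_redrawn, b - 1L
            ),
            class = "mrscore_bootstrap_error"
          )
        }
        next
      }
      draws[b, ] <- fit$coefficients[metabolites]
      b <- b + 1L
    }
  })
  ci <- tibble(
    term = metabolites,
    conf_low = apply(draws, 2, quantile, probs = 0.025, names = FALSE),
    conf_high = apply(draws, 2, quantile, probs = 0.975, names = FALSE)
  )
  structure(
    list(draws = as_tibble(draws), ci = ci,
         n_boot = as.integer(n_boot), n_redrawn = n_redrawn),
    class = "mrs_bootstrap"
  )
}

#' @export
print.mrs_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap weight stability (%d resamples, %d redrawn)\n",
              x$n_boot, x$n_redrawn))
  print(x$ci)
  invisible(x)
}

#' @method tidy mrs_bootstrap
#' @export
tidy.mrs_bootstrap <- function(x, ...) x$ci

#' Per-SD hazard-ratio bootstrap intervals
#'
#' Exponentiates the bootstrap weight distribution times the covariate SD,
#' the reporting scale of the published metabolite effects (their marked
#' asymmetry is a signature of the small-sample weight distribution).
#'
#' @param boot An `mrs_bootstrap`.
#' @param sds Named SDs for (a subset of) the bootstrapped metabolites.
#' @return Tibble: term, sd, hr, conf_low, conf_high (HR scale).
#' @export
bootstrap_hr_per_sd <- function(boot, sds) {
  terms <- intersect(names(sds), names(boot$draws))
  if (!length(terms)) stop_invalid("`sds` names do not match bootstrapped terms.")
  purrr::map_dfr(terms, function(v) {
    hr_draws <- exp(boot$draws[[v]] * sds[[v]])
    tibble(
      term = v, sd = sds[[v]],
      hr = median(hr_draws),
      conf_low = quantile(hr_draws, 0.025, names = FALSE),
      conf_high = quantile(hr_draws, 0.975, names = FALSE)
    )
  })
}

#' Serialize a risk-score model to JSON (and back)
#'
#' Versioned schema `{version, names, means, betas, lambda, gamma, t,
#' boot_ci, n_boot}` at full precision; a reloaded model scores patients
#' bit-identically.
#'
#' @param model An `mrs_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `mrs_to_json()`: `path` (invisibly) or a JSON string;
#'   `mrs_from_json()`: an `mrs_model`.
#' @export
mrs_to_json <- function(model, path = NULL) {
  payload <- list(
    format = "mrscore_mrs_model", version = 1L,
    names = model$metabolites,
    means = unname(model$means),
    betas = unname(model$betas),
    lambda = model$lambda, gamma = model$gamma, t = model$t,
    boot_ci = model$boot_ci,
    n_boot = if (is.na(model$n_boot)) NULL else model$n_boot
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname mrs_to_json
#' @export
mrs_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  m <- mrs_model(
    metabolites = x$names, means = x$means, betas = x$betas,
    lambda = x$lambda, gamma = x$gamma, t = x$t
  )
  if (!is.null(x$boot_ci) && length(x$boot_ci)) {
    m$boot_ci <- as_tibble(x$boot_ci)
    m$n_boot <- x$n_boot %||% NA_integer_
  }
  m
}

#' @export
print.mrs_model <- function(x, ...) {
  s0 <- baseline_survivor(x$lambda, x$gamma, x$t)
  terms <- sprintf("%+.4g (%s - %.4g)", unname(x$betas), x$metabolites,
                   unname(x$means))
  cat("Metabolite risk score\n")
  cat(sprintf("  MRS = 1 - %.4f ^ exp{ %s }\n", s0, paste(terms, collapse = " ")))
  cat(sprintf("  baseline Weibull scale %.4f, shape %.4f, horizon %g y\n",
              x$lambda, x$gamma, x$t))
  if (!is.null(x$boot_ci)) {
    cat(sprintf("  bootstrap weight 95%% CIs (%d resamples):\n", x$n_boot))
    print(x$boot_ci)
  }
  invisible(x)
}

#' @method tidy mrs_model
#' @export
tidy.mrs_model <- function(x, ...) {
  out <- tibble(
    term = x$metabolites,
    mean = unname(x$means),
    estimate = unname(x$betas)
  )
  if (!is.null(x$boot_ci)) out <- dplyr::left_join(out, x$boot_ci, by = "term")
  out
}

#' @method glance mrs_model
#' @export
glance.mrs_model <- function(x, ...) {
  tibble(
    lambda = x$lambda, gamma = x$gamma, t = x$t,
    baseline_survivor = baseline_survivor(x$lambda, x$gamma, x$t),
    n_metabolites = length(x$metabolites), n_boot = x$n_boot
  )
}
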