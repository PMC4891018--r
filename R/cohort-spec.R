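#' Specify a synthetic survival cohort
#'
#' A cohort specification fixes everything the generator needs: the number of
#' patients, the metabolite marginals (Normal, truncated at zero, in umol/L),
#' the true proportional-hazards coefficients driving the event times, the
#' baseline Weibull scale/shape pair of `S0(t) = exp{-(lambda * t)^gamma}`,
#' the administrative censoring horizon, per-metabolite MCAR missingness
#' probabilities, and a count of pure-noise covariates used for importance
#' specificity checks.
#'
#' @param n_patients Number of patients (positive integer).
#' @param metabolite_names Character vector of metabolite identifiers.
#' @param means,sds Per-metabolite concentration mean and SD (umol/L; SDs > 0).
#' @param betas Per-metabolite true PH coefficient, per umol/L. The linear
#'   predictor is centered at `means`.
#' @param lambda0,gamma0 Baseline Weibull scale (per year) and shape.
#' @param censor_time_max Administrative censoring horizon in years; censoring
#'   times are uniform on (0, `censor_time_max`].
#' @param missing_rates Per-metabolite MCAR probability in `[0, 1)`; recycled
#'   to the number of metabolites.
#' @param n_noise_covariates Number of standard-normal noise covariates,
#'   independent of the outcome.
#' @param seed Integer seed; the same spec always generates the same cohort.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [pdac_cohort_spec()]
#' @export
cohort_spec <- function(n_patients,
                        metabolite_names,
                        means,
                        sds,
                        betas,
                        lambda0 = 1.7376,
                        gamma0 = 1.0769,
                        censor_time_max = 1.25,
                        missing_rates = 0,
                        n_noise_covariates = 0,
                        seed = 1L) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 1 ||
      n_patients != as.integer(n_patients)) {
    stop_invalid("`n_patients` must be a positive integer.")
  }
  p <- length(metabolite_names)
  if (p < 1) stop_invalid("At least one metabolite is required.")
  if (length(missing_rates) == 1) missing_rates <- rep(missing_rates, p)
  lens <- c(length(means), length(sds), length(betas), length(missing_rates))
  if (any(lens != p)) {
    stop_invalid(
      "Lengths of `metabolite_names`, `means`, `sds`, `betas` and `missing_rates` must agree."
    )
  }
  if (any(sds <= 0)) stop_invalid("All `sds` must be strictly positive.")
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop_invalid("`missing_rates` must lie in [0, 1).")
  }
  if (lambda0 <= 0 || gamma0 <= 0) {
    stop_invalid("`lambda0` and `gamma0` must be strictly positive.")
  }
  if (censor_time_max <= 0) stop_invalid("`censor_time_max` must be positive.")
  if (n_noise_covariates < 0) stop_invalid("`n_noise_covariates` must be >= 0.")
  structure(
    list(
      n_patients = as.integer(n_patients),
      metabolite_names = as.character(metabolite_names),
      means = as.numeric(means),
      sds = as.numeric(sds),
      betas = as.numeric(betas),
      lambda0 = lambda0,
      gamma0 = gamma0,
      censor_time_max = censor_time_max,
      missing_rates = as.numeric(missing_rates),
      n_noise_covariates = as.integer(n_noise_covariates),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Cohort specification mirroring the pancreatic-adenocarcinoma study setting
#'
#' Defaults describe the development setting this package emulates: a small
#' pancreatic adenocarcinoma cohort (27 patients, roughly 2/3 one-year
#' mortality) whose survival is driven by five serum metabolites --- valine,
#' sphingomyelin C24:1, lysine, tripentadecanoate (TG15) and symmetric
#' dimethylarginine (SDMA) --- with published concentration means
#' (249.84, 23.93, 200.53, 8.46, 0.76 umol/L), SDs (98.57, 20.67, 51.73,
#' 2.88, 0.62) and centered Weibull-PH coefficients (-0.005, 0.047, -0.020,
#' -0.483, 1.314), around a baseline Weibull with scale 1.7376 and shape
#' 1.0769.
#'
#' @param n_patients Cohort size; default 27.
#' @param seed Integer seed.
#' @param ... Passed on to [cohort_spec()] to override any default.
#' @return A `cohort_spec`.
#' @export
pdac_cohort_spec <- function(n_patients = 27, seed = 1L, ...) {
  args <- list(
    n_patients = n_patients,
    metabolite_names = c("valine", "smc24_1", "lysine", "tg15", "sdma"),
    means = c(249.84, 23.93, 200.53, 8.46, 0.76),
    sds = c(98.57, 20.67, 51.73, 2.88, 0.62),
    betas = c(-0.005, 0.047, -0.020, -0.483, 1.314),
    lambda0 = 1.7376,
    gamma0 = 1.0769,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  patients:", x$n_patients,
      " seed:", x$seed,
      " noise covariates:", x$n_noise_covariates, "\n")
  cat("  baseline Weibull: scale", x$lambda0, "shape", x$gamma0,
      "; censoring horizon", x$censor_time_max, "y\n")
  tab <- tibble(
    metabolite = x$metabolite_names, mean = x$means, sd = x$sds,
    beta = x$betas, missing_rate = x$missing_rates
  )
  print(tab, n = min(nrow(tab), 10))
  invisible(x)
}
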