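#' Configure an end-to-end risk-score pipeline run
#'
#' Collects everything a reproducible run needs: the input cohort (a CSV
#' path, a data frame, or a [cohort_spec()] to simulate), column roles, the
#' forest configuration, stepwise thresholds, bootstrap size, prediction
#' horizon and per-stage seeds.
#'
#' @param input CSV path, data frame, or `cohort_spec`.
#' @param metabolites Metabolite column names (candidate predictors).
#' @param clinical Optional clinical column names (confounders).
#' @param time_col,event_col Outcome column names.
#' @param forest A [forest_config()].
#' @param p_enter,p_stay Stepwise thresholds.
#' @param importance_threshold Relative-importance screen (default 0.20).
#' @param n_boot Bootstrap resamples for weight stability (default 500 at
#'   desk scale; the published analysis used 10,000).
#' @param horizon Prediction horizon in years.
#' @param seeds Named list of integer seeds: `forest`, `bootstrap`,
#'   `evaluation` (all mandatory --- the reproducibility contract).
#' @param check_linearity Run the FP2 linearity check on each selected
#'   metabolite?
#' @param check_interactions Run the RECPAM interaction check on the
#'   selected metabolites?
#' @param output_dir Optional directory for artifacts (CSV tables, JSON
#'   models, run log).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            metabolites,
                            clinical = character(0),
                            time_col = "time_years",
                            event_col = "event",
                            forest = forest_config(),
                            p_enter = 0.10,
                            p_stay = 0.05,
                            importance_threshold = 0.20,
                            n_boot = 500,
                            horizon = 1,
                            seeds = list(forest = 1L, bootstrap = 2L, evaluation = 3L),
                            check_linearity = TRUE,
                            check_interactions = TRUE,
                            output_dir = NULL) {
  for (s in c("forest", "bootstrap", "evaluation")) {
    if (is.null(seeds[[s]])) {
      stop_invalid(paste0("Stage seed `", s, "` must be set explicitly."))
    }
  }
  if (!length(metabolites)) stop_invalid("`metabolites` must name at least one column.")
  structure(
    list(input = input, metabolites = metabolites, clinical = clinical,
         time_col = time_col, event_col = event_col, forest = forest,
         p_enter = p_enter, p_stay = p_stay,
         importance_threshold = importance_threshold,
         n_boot = n_boot, horizon = horizon,
         seeds = purrr::map(seeds, as.integer),
         check_linearity = check_linearity,
         check_interactions = check_interactions,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]; an embedded `spec:` block is turned
#' into a [cohort_spec()] (its `seed` is mandatory), an `input:` entry is a
#' CSV path, and a `forest:` block into a [forest_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$spec)) {
    if (is.null(y$spec$seed)) stop_invalid("`spec.seed` is mandatory in pipeline configs.")
    do.call(cohort_spec, y$spec)
  } else if (!is.null(y$input)) {
    y$input
  } else {
    stop_invalid("Config must provide `input:` (CSV path) or `spec:` (synthetic cohort).")
  }
  forest <- if (!is.null(y$forest)) do.call(forest_config, y$forest) else forest_config()
  args <- list(
    input = input, metabolites = y$metabolites,
    clinical = y$clinical %||% character(0),
    time_col = y$time_col %||% "time_years",
    event_col = y$event_col %||% "event",
    forest = forest,
    seeds = y$seeds %||% list()
  )
  for (opt in c("p_enter", "p_stay", "importance_threshold", "n_boot",
                "horizon", "check_linearity", "check_interactions", "output_dir")) {
    if (!is.null(y[[opt]])) args[[opt]] <- y[[opt]]
  }
  do.call(pipeline_config, args)
}

# dummy-code categorical covariates so they can enter a Weibull fit
expand_covariates <- function(data, vars) {
  cols <- character(0)
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      cols <- c(cols, v)
    } else {
      mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
      nms <- paste0(v, "_", sub("^x", "", colnames(mm)))
      for (k in seq_along(nms)) data[[nms[k]]] <- mm[, k]
      cols <- c(cols, nms)
    }
  }
  list(data = data, cols = cols)
}

# order-insensitive content checksum for the run log (no external digest dep)
content_checksum <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(str(x, vec.len = 1e6)), collapse = "\n"))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 997)) %% .Machine$integer.max)
}

#' Run the three-step risk-score pipeline end to end
#'
#' Executes, in order: cohort loading (or simulation), the 25% missingness
#' screen, forest-based imputation of remaining holes, the random survival
#' forest with permutation importance and the relative-importance screen,
#' stepwise Weibull selection (with optional FP2 linearity and RECPAM
#' interaction checks), risk-score construction with bootstrap weight
#' stability, RECPAM risk-class discovery on the score, and evaluation
#' (censored concordance, mortality rate, Kaplan-Meier by class).  When
#' clinical confounders are configured, the selected-metabolite model is
#' refitted adjusting for them one by one and all together, and the
#' coefficient stability tabulated.
#'
#' Every stage is a pure function of (input data, config, seeds); rerunning
#' an identical config reproduces every number.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `mrs_pipeline_report` with elements `screen`,
#'   `importance`, `screened_metabolites`, `stepwise`, `linearity`,
#'   `interaction`, `mrs` (the [mrs_model()]), `bootstrap`, `classes` (a
#'   [fit_recpam()] tree on the score), `evaluation`, `adjustment`, `data`
#'   (the scored cohort) and `log` (character).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a `pipeline_config`.")
  }
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), line))
  }
  fail_stage <- function(stage, e) {
    abort(paste0("Pipeline stage `", stage, "` failed: ", conditionMessage(e)),
          class = "mrscore_pipeline_error", parent = e)
  }

  # stage: data ------------------------------------------------------------
  data <- tryCatch({
    if (inherits(config$input, "cohort_spec")) {
      generate_cohort(config$input)
    } else if (is.character(config$input)) {
      read_cohort_csv(config$input)
    } else if (is.data.frame(config$input)) {
      as_tibble(config$input)
    } else {
      stop_invalid("`input` must be a CSV path, data frame or cohort_spec.")
    }
  }, error = function(e) fail_stage("data", e))
  tryCatch(
    check_outcome(data, config$time_col, config$event_col),
    error = function(e) fail_stage("data", e)
  )
  check_covariates_present(data, config$metabolites)
  say("data: %d patients, %d events [%s]", nrow(data),
      sum(data[[config$event_col]]), content_checksum(dim(data)))

  # stage: missingness screen ----------------------------------------------
  screen <- tryCatch(
    screen_covariates(data, config$metabolites,
                      config$forest$missing_rate_threshold),
    error = function(e) fail_stage("screen", e)
  )
  retained <- screen$covariate[screen$retained]
  say("screen: %d/%d covariates retained", length(retained), nrow(screen))
  if (!length(retained)) fail_stage("screen", simpleError("no covariate survives the missingness screen"))

  # stage: imputation ------------------------------------------------------
  data_imp <- tryCatch(
    impute_missing_in_forest(data, retained, config$forest,
                             config$time_col, config$event_col),
    error = function(e) fail_stage("impute", e)
  )

  # stage: forest + importance screen ---------------------------------------
  fcfg <- config$forest
  fcfg$seed <- config$seeds$forest
  forest <- tryCatch(
    grow_forest(data_imp, retained, fcfg, config$time_col, config$event_col),
    error = function(e) fail_stage("forest", e)
  )
  vimp <- permutation_importance(forest)
  screened <- apply_importance_screen(vimp, config$importance_threshold)
  say("forest: OOB error %.4f; %d covariates pass the %.0f%% importance screen",
      forest$oob_error, length(screened), 100 * config$importance_threshold)

  # stage: stepwise Weibull -------------------------------------------------
  sel <- tryCatch(
    stepwise_select(data_imp, screened, config$time_col, config$event_col,
                    config$p_enter, config$p_stay),
    error = function(e) fail_stage("stepwise", e)
  )
  say("stepwise: selected {%s}, AIC %.3f",
      paste(sel$selected, collapse = ", "), sel$fit$aic)

  linearity <- NULL
  if (config$check_linearity && length(sel$selected) &&
      sum(data_imp[[config$event_col]]) >= 10) {
    linearity <- purrr::map(sel$selected, function(v) {
      tryCatch(fp2_linearity_check(data_imp, v, config$time_col, config$event_col),
               error = function(e) NULL)
    })
    names(linearity) <- sel$selected
    say("linearity: %s", paste(
      purrr::imap_chr(linearity, ~ paste0(.y, "=", if (is.null(.x)) "NA" else .x$verdict)),
      collapse = " "
    ))
  }
  interaction <- NULL
  if (config$check_interactions && length(sel$selected) >= 2) {
    interaction <- tryCatch(
      interaction_check(data_imp, sel$selected, config$time_col, config$event_col),
      error = function(e) NULL
    )
    if (!is.null(interaction)) say("interaction: %s", interaction$verdict)
  }

  # stage: risk score -------------------------------------------------------
  report <- tryCatch({
    empty_fit <- fit_weibull_ph(data_imp, character(0),
                                config$time_col, config$event_col)
    score_vars <- if (length(sel$selected)) sel$selected else screened
    if (!length(score_vars)) stop_invalid("No metabolites available for the score.")
    multi_fit <- fit_weibull_ph(data_imp, score_vars,
                                config$time_col, config$event_col, center = TRUE)
    boot <- bootstrap_weights(data_imp, score_vars,
                              n_boot = max(config$n_boot, 100),
                              seed = config$seeds$bootstrap,
                              time_col = config$time_col,
                              event_col = config$event_col)
    model <- build_mrs(empty_fit, multi_fit, t = config$horizon, bootstrap = boot)
    scored <- compute_mrs(data_imp, model)
    list(empty_fit = empty_fit, multi_fit = multi_fit, boot = boot,
         model = model, scored = scored)
  }, error = function(e) fail_stage("mrs", e))
  say("mrs: score built on {%s} [%s]",
      paste(report$model$metabolites, collapse = ", "),
      content_checksum(report$model$betas))

  # stage: risk classes -----------------------------------------------------
  classes <- tryCatch(
    fit_recpam(report$scored, splitting_vars = "mrs",
               time_col = config$time_col, event_col = config$event_col),
    error = function(e) fail_stage("classes", e)
  )
  scored <- report$scored
  scored$risk_class <- factor(classes$assignments)
  say("classes: %d risk class(es)", nrow(classes$classes))

  # stage: evaluation -------------------------------------------------------
  evaluation <- tryCatch({
    cstat <- cstat_censored(scored, scored$mrs, config$time_col,
                            config$event_col, seed = config$seeds$evaluation)
    rate <- mortality_rate(scored, horizon = config$horizon,
                           config$time_col, config$event_col)
    km <- kaplan_meier(scored, by = "risk_class",
                       time_col = config$time_col, event_col = config$event_col)
    list(cstat = cstat, mortality = rate, km = km)
  }, error = function(e) fail_stage("evaluate", e))
  say("evaluate: c-statistic %.3f; %.1f deaths per 100 py within %g y",
      evaluation$cstat$c_statistic, evaluation$mortality$rate_per_100py,
      config$horizon)

  # stage: confounder adjustment --------------------------------------------
  adjustment <- NULL
  if (length(config$clinical) && length(sel$selected)) {
    adjustment <- tryCatch({
      ex <- expand_covariates(scored, config$clinical)
      adj_sets <- c(
        purrr::map(config$clinical, ~ expand_covariates(scored, .x)$cols),
        list(ex$cols)
      )
      names(adj_sets) <- c(config$clinical, "all_together")
      purrr::imap_dfr(c(list(unadjusted = character(0)), adj_sets), function(extra, nm) {
        f <- suppressWarnings(
          fit_weibull_ph(ex$data, c(sel$selected, extra),
                         config$time_col, config$event_col)
        )
        dplyr::filter(tidy(f), .data$term %in% sel$selected) |>
          dplyr::mutate(adjustment = nm, .before = 1)
      })
    }, error = function(e) NULL)
  }

  out <- structure(
    list(
      config = config, screen = screen, importance = vimp,
      screened_metabolites = screened, stepwise = sel,
      linearity = linearity, interaction = interaction,
      mrs = report$model, bootstrap = report$boot,
      empty_fit = report$empty_fit, multivariable_fit = report$multi_fit,
      classes = classes, evaluation = evaluation,
      adjustment = adjustment, data = scored, log = log_lines
    ),
    class = "mrs_pipeline_report"
  )
  if (!is.null(config$output_dir)) write_pipeline_artifacts(out, config$output_dir)
  out
}

write_pipeline_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(report$data, file.path(dir, "cohort_scored.csv"))
  write.csv(report$importance, file.path(dir, "importance.csv"), row.names = FALSE)
  mrs_to_json(report$mrs, file.path(dir, "mrs_model.json"))
  weibull_fit_to_json(report$multivariable_fit, file.path(dir, "weibull_fit.json"))
  recpam_to_json(report$classes, file.path(dir, "risk_classes.json"))
  summary_json <- list(
    selected = report$stepwise$selected,
    screened = report$screened_metabolites,
    c_statistic = report$evaluation$cstat$c_statistic,
    mortality_rate_per_100py = report$evaluation$mortality$rate_per_100py,
    n_classes = nrow(report$classes$classes),
    class_hr = report$classes$classes$hr
  )
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.mrs_pipeline_report <- function(x, ...) {
  cat("Metabolite risk-score pipeline report\n")
  cat("  screened metabolites:", paste(x$screened_metabolites, collapse = ", "), "\n")
  cat("  selected:", if (length(x$stepwise$selected))
    paste(x$stepwise$selected, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  c-statistic: %.3f (%.3f-%.3f)\n",
              x$evaluation$cstat$c_statistic,
              x$evaluation$cstat$conf_low, x$evaluation$cstat$conf_high))
  cat(sprintf("  one-year mortality: %.1f per 100 person-years\n",
              x$evaluation$mortality$rate_per_100py))
  cat(sprintf("  risk classes: %d\n", nrow(x$classes$classes)))
  invisible(x)
}
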