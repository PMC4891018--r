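#' Random survival forest configuration
#'
#' @param n_trees Number of survival trees (desk default 1,000; the published
#'   analysis scale is 100,000 --- importance ranks stabilise far below that
#'   on small cohorts).
#' @param mtry Covariates tried per split; default `ceiling(sqrt(p))`.
#' @param min_terminal_events Minimum node size at which splitting stops
#'   (mapped to the tree grower's node-size control; an event-count bound is
#'   not available in the backend).
#' @param seed Integer seed; forests are deterministic given the seed.
#' @param missing_rate_threshold Exclusion cut-off for the missingness
#'   screen, in (0, 1]; default 0.25.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000, mtry = NULL, min_terminal_events = 3,
                          seed = 1L, missing_rate_threshold = 0.25) {
  if (n_trees < 1) stop_invalid("`n_trees` must be at least 1.")
  if (!is.null(mtry) && mtry < 1) stop_invalid("`mtry` must be at least 1.")
  if (missing_rate_threshold <= 0 || missing_rate_threshold > 1) {
    stop_invalid("`missing_rate_threshold` must lie in (0, 1].")
  }
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry,
         min_terminal_events = as.integer(min_terminal_events),
         seed = as.integer(seed),
         missing_rate_threshold = missing_rate_threshold),
    class = "forest_config"
  )
}

#' Screen covariates by missingness
#'
#' Covariates whose missing fraction strictly exceeds the threshold are
#' excluded from all further analysis; a fraction exactly at the threshold is
#' retained (the rule is "higher than 25%").
#'
#' @param data Cohort data frame.
#' @param covariates Covariate columns to screen.
#' @param threshold Exclusion cut-off (default 0.25).
#' @return A tibble (covariate, missing_rate, retained), ordered as given.
#' @export
screen_covariates <- function(data, covariates, threshold = 0.25) {
  check_covariates_present(data, covariates)
  rates <- purrr::map_dbl(covariates, ~ mean(is.na(data[[.x]])))
  tibble(
    covariate = covariates,
    missing_rate = rates,
    retained = rates <= threshold
  )
}

#' Grow a random survival forest
#'
#' Each tree is grown on a with-replacement bootstrap of the patients
#' (leaving ~36.8% out of bag), log-rank statistics choose the splits, and
#' the out-of-bag error is one minus the censoring-aware OOB ensemble
#' concordance.  The forest is grown by \pkg{ranger} and is deterministic
#' given the config seed.
#'
#' @param data Cohort data frame with no missing values among `covariates`
#'   (run [impute_missing_in_forest()] first if needed).
#' @param covariates Covariate columns.
#' @param config A [forest_config()].
#' @param time_col,event_col Outcome columns.
#' @return A list of class `mrs_forest`: the fitted `ranger` object,
#'   `covariates`, `config` and `oob_error`.
#' @export
grow_forest <- function(data, covariates, config = forest_config(),
                        time_col = "time_years", event_col = "event") {
  check_outcome(data, time_col, event_col)
  check_covariates_present(data, covariates)
  if (sum(data[[event_col]]) < 2) stop_invalid("At least two events are required.")
  if (anyNA(data[covariates])) {
    stop_invalid("Missing covariate values: impute before growing the forest.")
  }
  df <- data.frame(
    ..time = data[[time_col]], ..event = data[[event_col]],
    data[covariates], check.names = FALSE
  )
  rf <- ranger::ranger(
    formula = survival::Surv(..time, ..event) ~ .,
    data = df,
    num.trees = config$n_trees,
    mtry = config$mtry %||% ceiling(sqrt(length(covariates))),
    min.node.size = max(config$min_terminal_events, 1L),
    splitrule = "logrank",
    importance = "permutation",
    seed = config$seed,
    num.threads = 1
  )
  structure(
    list(ranger = rf, covariates = covariates, config = config,
         oob_error = rf$prediction.error),
    class = "mrs_forest"
  )
}

#' @export
print.mrs_forest <- function(x, ...) {
  cat(sprintf(
    "Random survival forest: %d trees, %d covariates, OOB error = %.4f\n",
    x$config$n_trees, length(x$covariates), x$oob_error
  ))
  invisible(x)
}

#' Breiman-Cutler permutation importance
#'
#' Importance of a covariate is the increase in out-of-bag prediction error
#' when its out-of-bag values are randomly permuted while all others are left
#' unchanged.  Relative importance is the ratio of each score to the score of
#' the first-ranked covariate, so the top covariate has relative importance
#' exactly 1; negative scores (noise) are clipped at 0 for screening.
#'
#' @param forest An `mrs_forest`.
#' @return A tibble of class `mrs_vimp`: covariate, score,
#'   relative_importance, rank (by decreasing score).
#' @export
permutation_importance <- function(forest) {
  if (!inherits(forest, "mrs_forest")) stop_invalid("`forest` must be an `mrs_forest`.")
  vi <- forest$ranger$variable.importance
  top <- max(vi)
  rel <- if (top > 0) pmax(vi, 0) / top else rep(0, length(vi))
  out <- tibble(
    covariate = names(vi),
    score = unname(vi),
    relative_importance = unname(rel)
  ) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("mrs_vimp", class(out))
  out
}

#' Select covariates by relative importance
#'
#' @param vimp An `mrs_vimp` table.
#' @param threshold Relative-importance cut-off (default 0.20, the "at least
#'   20%" metabolite screen; the clinical-variable screen used "greater than
#'   34%", i.e. `threshold = 0.34, strictly_greater = TRUE`).
#' @param strictly_greater Require strictly greater than `threshold` instead
#'   of at-least?
#' @return Character vector of selected covariates in rank order.
#' @export
apply_importance_screen <- function(vimp, threshold = 0.20,
                                    strictly_greater = FALSE) {
  keep <- if (strictly_greater) {
    vimp$relative_importance > threshold
  } else {
    vimp$relative_importance >= threshold
  }
  vimp$covariate[keep]
}

#' Forest-based imputation of missing covariate values
#'
#' Completes MCAR holes by exploiting the forest's grouping of patients:
#' missing cells are first filled by seeded random draws from the observed
#' values of the same column, a forest is grown on the completed data, and
#' each missing cell is then re-imputed by aggregating the observed values of
#' the patients sharing its terminal node, tree by tree (mean for numeric
#' columns, mode for categorical), iterating the grow/re-impute cycle.
#' Observed values are never touched, and a dataset without missing values is
#' returned bit-identical.
#'
#' @param data Cohort data frame.
#' @param covariates Covariate columns to complete.
#' @param config A [forest_config()]; its `missing_rate_threshold` bounds the
#'   admissible per-covariate missing rate.
#' @param time_col,event_col Outcome columns.
#' @param n_iter Grow/re-impute cycles (default 2).
#' @return `data` with all `covariates` complete.
#' @export
impute_missing_in_forest <- function(data, covariates, config = forest_config(),
                                     time_col = "time_years", event_col = "event",
                                     n_iter = 2L) {
  check_outcome(data, time_col, event_col)
  check_covariates_present(data, covariates)
  miss <- purrr::map_lgl(covariates, ~ anyNA(data[[.x]]))
  if (!any(miss)) return(data)
  rates <- purrr::map_dbl(covariates, ~ mean(is.na(data[[.x]])))
  if (any(rates >= 1)) {
    stop_invalid("A covariate is missing for all patients; it cannot be imputed.")
  }
  if (any(rates > config$missing_rate_threshold)) {
    stop_invalid(paste0(
      "Missing rate above the exclusion threshold for: ",
      paste(covariates[rates > config$missing_rate_threshold], collapse = ", "),
      ". Screen covariates first."
    ))
  }
  n <- nrow(data)
  na_idx <- purrr::map(covariates, ~ which(is.na(data[[.x]])))
  names(na_idx) <- covariates
  work <- data
  withr::with_seed(config$seed, {
    # marginal-draw initialisation
    for (v in covariates) {
      idx <- na_idx[[v]]
      if (length(idx)) {
        obs <- work[[v]][-idx]
        work[[v]][idx] <- sample(obs, length(idx), replace = TRUE)
      }
    }
    for (iter in seq_len(n_iter)) {
      forest <- grow_forest(work, covariates, config, time_col, event_col)
      tn <- stats::predict(
        forest$ranger,
        data = data.frame(work[covariates], check.names = FALSE),
        type = "terminalNodes", num.threads = 1
      )$predictions # n x trees
      for (v in covariates) {
        idx <- na_idx[[v]]
        if (!length(idx)) next
        observed_mask <- !seq_len(n) %in% idx
        vals <- data[[v]]
        numeric_col <- is.numeric(vals)
        for (i in idx) {
          donor_pool <- list()
          agg <- if (numeric_col) numeric(0) else character(0)
          for (b in seq_len(ncol(tn))) {
            donors <- which(tn[, b] == tn[i, b] & observed_mask)
            if (length(donors)) {
              agg <- c(agg, if (numeric_col) mean(vals[donors]) else
                as.character(stat_mode(vals[donors])))
            }
          }
          if (length(agg)) {
            work[[v]][i] <- if (numeric_col) mean(agg) else stat_mode(agg)
          } else {
            work[[v]][i] <- if (numeric_col) mean(vals[observed_mask]) else
              stat_mode(vals[observed_mask])
          }
        }
      }
    }
  })
  work
}

#' Two-sample log-rank statistic
#'
#' Textbook log-rank (Mantel-Haenszel) chi-squared statistic for comparing
#' two survival curves --- the split criterion of the survival trees.  At
#' each distinct event time the observed number of events in group 1 is
#' compared with its hypergeometric expectation given the risk sets.
#'
#' @param time,event Follow-up times and 0/1 event flags.
#' @param group Logical or 0/1 vector defining the two groups.
#' @return The chi-squared statistic (1 df); `NA` when a group is empty or
#'   no events occur.
#' @export
logrank_split_statistic <- function(time, event, group) {
  g <- as.logical(group)
  if (!any(g) || all(g)) return(NA_real_)
  dt <- sort(unique(time[event == 1]))
  if (!length(dt)) return(NA_real_)
  o_minus_e <- 0
  v <- 0
  for (tj in dt) {
    at_risk <- time >= tj
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g)
    d_j <- sum(event == 1 & time == tj)
    d1_j <- sum(event == 1 & time == tj & g)
    o_minus_e <- o_minus_e + d1_j - d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  if (v <= 0) return(NA_real_)
  o_minus_e^2 / v
}
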