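#' Censored-data concordance of a risk prediction
#'
#' Harrell-type concordance on predicted event probabilities: a pair of
#' patients is usable when the shorter observed time ends in an event, and
#' counts as concordant when the higher predicted risk belongs to the
#' patient failing earlier; ties in risk count one half.  The 95% CI comes
#' from a seeded patient-level bootstrap.
#'
#' @param data Cohort data frame.
#' @param risk Either a numeric vector of per-patient predicted one-year
#'   mortality probabilities (any monotone risk score works) or the name of
#'   a column of `data`.
#' @param time_col,event_col Outcome columns.
#' @param n_boot Bootstrap resamples for the CI (default 1000; 0 skips it).
#' @param seed Integer seed.
#' @return A one-row tibble of class `mrs_concordance`: `c_statistic`,
#'   `conf_low`, `conf_high`, `n_pairs` (usable pairs), `n_tied_risk`.
#' @export
cstat_censored <- function(data, risk, time_col = "time_years",
                           event_col = "event", n_boot = 1000, seed = 1L) {
  check_outcome(data, time_col, event_col)
  if (is.character(risk) && length(risk) == 1) {
    check_covariates_present(data, risk)
    risk <- data[[risk]]
  }
  if (length(risk) != nrow(data)) {
    stop_invalid("`risk` must have one value per patient.")
  }
  if (anyNA(risk) || any(!is.finite(risk))) stop_invalid("`risk` must be finite.")
  time <- data[[time_col]]
  event <- data[[event_col]]
  cfit <- survival::concordance(
    survival::Surv(time, event) ~ risk, reverse = TRUE
  )
  counts <- cfit$count
  n_pairs <- unname(counts["concordant"] + counts["discordant"] + counts["tied.x"])
  if (n_pairs < 1 || is.nan(cfit$concordance)) {
    stop_invalid("No usable pairs: the concordance is undefined.")
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot_c <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(time), replace = TRUE)
        cb <- tryCatch(
          survival::concordance(
            survival::Surv(time[idx], event[idx]) ~ risk[idx], reverse = TRUE
          )$concordance,
          error = function(e) NA_real_
        )
        cb
      }, numeric(1))
    })
    ci <- quantile(boot_c, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    ci <- pmin(pmax(ci, 0), 1)
  }
  out <- tibble(
    c_statistic = unname(cfit$concordance),
    conf_low = ci[1], conf_high = ci[2],
    n_pairs = n_pairs,
    n_tied_risk = unname(counts["tied.x"])
  )
  class(out) <- c("mrs_concordance", class(out))
  out
}

#' Compare two risk predictions by paired bootstrap
#'
#' Bootstraps patients jointly for both predictions, giving the empirical
#' distribution of the concordance difference; the two-sided p-value is read
#' from that distribution centered at zero.
#'
#' @param data Cohort data frame.
#' @param risk_a,risk_b Numeric risk vectors (or column names) on the same
#'   patients.
#' @param time_col,event_col Outcome columns.
#' @param n_boot Paired bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `c_a`, `c_b`, `difference`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
compare_cstats <- function(data, risk_a, risk_b, time_col = "time_years",
                           event_col = "event", n_boot = 1000, seed = 1L) {
  check_outcome(data, time_col, event_col)
  grab <- function(r) {
    if (is.character(r) && length(r) == 1) data[[r]] else r
  }
  risk_a <- grab(risk_a)
  risk_b <- grab(risk_b)
  if (length(risk_a) != nrow(data) || length(risk_b) != nrow(data)) {
    stop_invalid("Both risk vectors must have one value per patient.")
  }
  time <- data[[time_col]]
  event <- data[[event_col]]
  cone <- function(idx, r) {
    survival::concordance(
      survival::Surv(time[idx], event[idx]) ~ r[idx], reverse = TRUE
    )$concordance
  }
  all_idx <- seq_along(time)
  c_a <- cone(all_idx, risk_a)
  c_b <- cone(all_idx, risk_b)
  d_obs <- c_a - c_b
  d_boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(time), replace = TRUE)
      tryCatch(cone(idx, risk_a) - cone(idx, risk_b),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  d_boot <- d_boot[is.finite(d_boot)]
  centered <- d_boot - mean(d_boot)
  p <- (sum(abs(centered) >= abs(d_obs)) + 1) / (length(centered) + 1)
  ci <- quantile(d_boot, c(0.025, 0.975), names = FALSE)
  tibble(
    c_a = c_a, c_b = c_b, difference = d_obs,
    conf_low = ci[1], conf_high = ci[2], p_value = p
  )
}

#' Kaplan-Meier estimate as a tidy table
#'
#' Product-limit estimate of the survivor function, optionally stratified
#' (e.g. by RECPAM risk class), with per-time at-risk and event counts.
#'
#' @param data Cohort data frame.
#' @param by Optional stratification column name.
#' @param time_col,event_col Outcome columns.
#' @return A tibble of class `mrs_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `estimate`, `std_error`, and `strata` when `by` is given.
#' @export
kaplan_meier <- function(data, by = NULL, time_col = "time_years",
                         event_col = "event") {
  check_outcome(data, time_col, event_col, require_event = FALSE)
  if (nrow(data) < 1) stop_invalid("At least one patient is required.")
  surv <- survival::Surv(data[[time_col]], data[[event_col]])
  if (is.null(by)) {
    sf <- survival::survfit(surv ~ 1)
    out <- tibble(
      time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
      n_censor = sf$n.censor, estimate = sf$surv, std_error = sf$std.err
    )
  } else {
    check_covariates_present(data, by)
    grp <- factor(data[[by]])
    sf <- survival::survfit(surv ~ grp)
    strata_names <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
    out <- tibble(
      strata = strata_names,
      time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
      n_censor = sf$n.censor, estimate = sf$surv, std_error = sf$std.err
    )
  }
  class(out) <- c("mrs_km", class(out))
  out
}

#' Mortality rate per 100 person-years
#'
#' Events divided by accumulated person-time, times 100.  With a horizon,
#' follow-up is truncated there: a patient followed past the horizon
#' contributes horizon person-time and no event after it.
#'
#' @param data Cohort data frame.
#' @param horizon Optional truncation time in years (e.g. 1 for the
#'   one-year rate); `NULL` for the overall rate.
#' @param time_col,event_col Outcome columns.
#' @return One-row tibble: `events`, `person_years`, `rate_per_100py`.
#' @export
mortality_rate <- function(data, horizon = NULL, time_col = "time_years",
                           event_col = "event") {
  check_outcome(data, time_col, event_col, require_event = FALSE)
  time <- data[[time_col]]
  event <- data[[event_col]]
  if (!is.null(horizon)) {
    if (horizon <= 0) stop_invalid("`horizon` must be positive.")
    event <- as.integer(event == 1 & time <= horizon)
    time <- pmin(time, horizon)
  }
  py <- sum(time)
  if (py <= 0) stop_invalid("Zero total person-years: the rate is undefined.")
  tibble(
    events = sum(event),
    person_years = py,
    rate_per_100py = 100 * sum(event) / py
  )
}

#' Associations between clinical variables and metabolite levels
#'
#' For each (clinical variable, metabolite) pair: Spearman correlation when
#' the clinical variable is continuous, a Mann-Whitney rank-sum test when it
#' defines two groups, Kruskal-Wallis for three or more groups.  Constant
#' columns are flagged and their association recorded as undefined.  Raw
#' p-values are reported by default; `adjust = "BH"` applies
#' Benjamini-Hochberg across the table.
#'
#' @param data Cohort data frame.
#' @param clinical_vars Clinical columns (numeric or categorical).
#' @param metabolites Metabolite columns (numeric).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: clinical, metabolite, method, estimate (Spearman rho
#'   where applicable), statistic, p_value, note.
#' @export
clinical_associations <- function(data, clinical_vars, metabolites,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  check_covariates_present(data, c(clinical_vars, metabolites))
  rows <- list()
  for (cv in clinical_vars) {
    for (met in metabolites) {
      x <- data[[cv]]
      y <- data[[met]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]
      y <- y[ok]
      row <- tibble(clinical = cv, metabolite = met, method = NA_character_,
                    estimate = NA_real_, statistic = NA_real_,
                    p_value = NA_real_, note = NA_character_)
      if (length(unique(y)) < 2 || length(unique(x)) < 2) {
        row$note <- "undefined: constant column"
      } else if (is.numeric(x)) {
        ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
        row$method <- "spearman"
        row$estimate <- unname(ct$estimate)
        row$statistic <- unname(ct$statistic)
        row$p_value <- ct$p.value
      } else {
        g <- factor(x)
        if (nlevels(g) == 2) {
          wt <- suppressWarnings(wilcox.test(y ~ g, exact = FALSE))
          row$method <- "mann-whitney"
          row$statistic <- unname(wt$statistic)
          row$p_value <- wt$p.value
        } else {
          kt <- kruskal.test(y, g)
          row$method <- "kruskal-wallis"
          row$statistic <- unname(kt$statistic)
          row$p_value <- kt$p.value
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
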