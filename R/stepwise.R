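#' Stepwise selection of Weibull PH covariates
#'
#' Classical forward stepwise with backward checks, as used to pick the
#' score metabolites: at each forward step every candidate not yet in the
#' model is fitted on top of the current model and is entry-eligible when its
#' Wald p-value is at most `p_enter`; among eligible candidates the one whose
#' model minimises the AIC enters (ties broken by candidate order).  After
#' each entry, included covariates whose Wald p-value exceeds `p_stay` are
#' removed, worst first.  The procedure is deterministic given the data and
#' stops when no entry or removal is possible.
#'
#' @param data Cohort data frame; rows incomplete in any candidate are
#'   dropped (with a warning) before selection.
#' @param candidates Character vector of candidate covariates.
#' @param time_col,event_col Outcome columns.
#' @param p_enter,p_stay Entry / stay significance levels (defaults 0.10 and
#'   0.05).
#' @return A list of class `mrs_stepwise`: `selected` (character, in entry
#'   order), `fit` (the final `weibull_ph_fit`; the empty model when nothing
#'   enters), and `trace`, a tibble with one row per step (step, action,
#'   variable, p_value, aic).
#' @export
stepwise_select <- function(data, candidates,
                            time_col = "time_years", event_col = "event",
                            p_enter = 0.10, p_stay = 0.05) {
  check_outcome(data, time_col, event_col)
  check_covariates_present(data, candidates)
  if (length(candidates)) {
    cc <- complete.cases(data[candidates])
    if (!all(cc)) {
      warn(sprintf("Dropping %d incomplete row(s) before stepwise selection.", sum(!cc)))
      data <- data[cc, , drop = FALSE]
    }
    if (nrow(data) < 2 * length(candidates)) {
      warn("Fewer than 2 complete cases per candidate; selection may be unstable.")
    }
  }

  selected <- character(0)
  trace <- list()
  step_i <- 0L
  fit <- fit_weibull_ph(data, selected, time_col, event_col)
  seen <- character(0) # visited models, guards add/remove cycles

  repeat {
    key <- paste(sort(selected), collapse = "|")
    if (key %in% seen) break
    seen <- c(seen, key)
    changed <- FALSE
    # forward entry
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      stats_in <- purrr::map(pool, function(v) {
        f <- tryCatch(
          suppressWarnings(fit_weibull_ph(data, c(selected, v), time_col, event_col)),
          mrscore_validation_error = function(e) NULL, error = function(e) NULL
        )
        if (is.null(f) || !f$converged) return(NULL)
        list(var = v, p = f$wald$p.value[f$wald$term == v], aic = f$aic, fit = f)
      })
      stats_in <- purrr::compact(stats_in)
      eligible <- purrr::keep(stats_in, ~ is.finite(.x$p) && .x$p <= p_enter)
      if (length(eligible)) {
        aics <- purrr::map_dbl(eligible, "aic")
        best <- eligible[[which.min(aics)]] # which.min is first-on-tie
        selected <- c(selected, best$var)
        fit <- best$fit
        step_i <- step_i + 1L
        trace[[length(trace) + 1L]] <- tibble(
          step = step_i, action = "add", variable = best$var,
          p_value = best$p, aic = best$aic
        )
        changed <- TRUE
      }
    }
    # backward removal
    repeat {
      if (!length(selected)) break
      w <- fit$wald
      worst <- w[which.max(w$p.value), ]
      if (!is.finite(worst$p.value) || worst$p.value <= p_stay) break
      selected <- setdiff(selected, worst$term)
      fit <- fit_weibull_ph(data, selected, time_col, event_col)
      step_i <- step_i + 1L
      trace[[length(trace) + 1L]] <- tibble(
        step = step_i, action = "remove", variable = worst$term,
        p_value = worst$p.value, aic = fit$aic
      )
      changed <- TRUE
    }
    if (!changed) break
  }

  structure(
    list(
      selected = selected,
      fit = fit,
      trace = if (length(trace)) dplyr::bind_rows(trace) else
        tibble(step = integer(), action = character(), variable = character(),
               p_value = double(), aic = double())
    ),
    class = "mrs_stepwise"
  )
}

#' @export
print.mrs_stepwise <- function(x, ...) {
  cat("Stepwise Weibull PH selection\n")
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("  selected: (none)\n")
  }
  cat(sprintf("  final AIC: %.3f\n", x$fit$aic))
  if (nrow(x$trace)) print(x$trace)
  invisible(x)
}
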