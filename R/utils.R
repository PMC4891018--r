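# internal validation helpers ------------------------------------------------

stop_invalid <- function(msg, ...) {
  abort(msg, class = "mrscore_validation_error", ...)
}

# Checks the (time, event) outcome columns of a cohort data frame.
# times must be strictly positive, events coded 0/1.
check_outcome <- function(data, time_col, event_col, require_event = TRUE) {
  if (!is.data.frame(data)) {
    stop_invalid("`data` must be a data frame.")
  }
  for (col in c(time_col, event_col)) {
    if (!col %in% names(data)) {
      stop_invalid(paste0("Column `", col, "` not found in `data`."))
    }
  }
  time <- data[[time_col]]
  event <- data[[event_col]]
  if (anyNA(time) || anyNA(event)) {
    stop_invalid("Follow-up time and event indicator must not contain missing values.")
  }
  if (any(time <= 0)) {
    stop_invalid("All follow-up times must be strictly positive.")
  }
  if (!all(event %in% c(0, 1))) {
    stop_invalid("Event indicator must be coded 0 (censored) / 1 (death).")
  }
  if (require_event && sum(event) < 1) {
    stop_invalid("At least one event is required.")
  }
  invisible(TRUE)
}

check_covariates_present <- function(data, covariates) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    stop_invalid(paste0(
      "Covariate(s) not found in `data`: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# mode of a vector (for categorical imputation); ties broken by first occurrence
stat_mode <- function(x) {
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

# inverse-CDF draw from a Normal(mean, sd) truncated below at `lower`
rtruncnorm <- function(n, mean, sd, lower = 0) {
  p_lo <- pnorm(lower, mean, sd)
  u <- runif(n, p_lo, 1)
  qnorm(u, mean, sd)
}
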