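#' Weibull log-log diagnostic plot coordinates
#'
#' Under a Weibull baseline, `log(-log S(t))` is linear in `log t` with slope
#' equal to the shape parameter.  This computes the Kaplan-Meier estimate,
#' keeps the event times where it lies strictly inside (0, 1), and returns
#' the `(log t, log(-log S_KM(t)))` pairs together with the R-squared and
#' slope of their least-squares line as a goodness-of-parameterisation
#' scalar.
#'
#' @param data Cohort data frame.
#' @param time_col,event_col Outcome columns.
#' @return A tibble of class `mrs_loglog` with columns `log_time` and
#'   `cloglog`, and attributes `r_squared`, `slope`, `intercept`.
#' @export
weibull_loglog_diagnostic <- function(data, time_col = "time_years",
                                      event_col = "event") {
  check_outcome(data, time_col, event_col)
  sf <- survival::survfit(
    survival::Surv(data[[time_col]], data[[event_col]]) ~ 1
  )
  keep <- sf$n.event > 0 & sf$surv > 0 & sf$surv < 1
  if (sum(keep) < 2) {
    stop_invalid("At least two distinct event times with estimable survival are required.")
  }
  out <- tibble(
    log_time = log(sf$time[keep]),
    cloglog = log(-log(sf$surv[keep]))
  )
  fit <- lm(cloglog ~ log_time, data = out)
  attr(out, "r_squared") <- summary(fit)$r.squared
  attr(out, "slope") <- unname(coef(fit)[2])
  attr(out, "intercept") <- unname(coef(fit)[1])
  class(out) <- c("mrs_loglog", class(out))
  out
}

#' @export
print.mrs_loglog <- function(x, ...) {
  cat(sprintf(
    "Weibull log-log diagnostic: %d event times, R^2 = %.4f, slope (shape) = %.4f\n",
    nrow(x), attr(x, "r_squared"), attr(x, "slope")
  ))
  NextMethod()
}
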