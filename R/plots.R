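# ggplot2 displays for the main result types

#' @method autoplot mrs_km
#' @export
autoplot.mrs_km <- function(object, ...) {
  has_strata <- "strata" %in% names(object)
  # prepend time-zero anchors so every curve starts at S(0) = 1
  anchor <- if (has_strata) {
    dplyr::distinct(object, .data$strata) |>
      dplyr::mutate(time = 0, estimate = 1)
  } else {
    tibble(time = 0, estimate = 1)
  }
  df <- dplyr::bind_rows(anchor, object)
  p <- if (has_strata) {
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate,
                                     colour = .data$strata))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$estimate))
  }
  p +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (years)", y = "Survival probability",
                  colour = "Risk class") +
    ggplot2::theme_minimal()
}

#' @method autoplot mrs_vimp
#' @export
autoplot.mrs_vimp <- function(object, threshold = 0.20, ...) {
  df <- dplyr::mutate(object, covariate = stats::reorder(.data$covariate,
                                                         .data$relative_importance))
  ggplot2::ggplot(df, ggplot2::aes(.data$relative_importance, .data$covariate)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$relative_importance,
                                       yend = .data$covariate), colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "Relative variable importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot mrs_loglog
#' @export
autoplot.mrs_loglog <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$log_time, .data$cloglog)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(
      x = "log follow-up time",
      y = "log(-log KM survival)",
      subtitle = sprintf("R² = %.3f, slope = %.3f",
                         attr(object, "r_squared"), attr(object, "slope"))
    ) +
    ggplot2::theme_minimal()
}

#' Risk-score distribution by survivor status
#'
#' Boxplot of the computed score for patients who died versus survived
#' within follow-up --- the standard face-validity display of a mortality
#' score.
#'
#' @param data Scored cohort (needs an `mrs` column).
#' @param event_col Event column name.
#' @return A ggplot object.
#' @export
plot_mrs_distribution <- function(data, event_col = "event") {
  check_covariates_present(data, c("mrs", event_col))
  df <- dplyr::mutate(
    data,
    status = factor(ifelse(.data[[event_col]] == 1, "died", "survived"),
                    levels = c("survived", "died"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$status, .data$mrs)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Metabolite risk score") +
    ggplot2::theme_minimal()
}
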