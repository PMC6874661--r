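# ggplot2 figure helpers: stage-wise survival curves, the daily-mortality
# bar chart, and the sensitivity chart with bootstrap error bars.

#' Plot product-limit survival curves by stage
#'
#' Step curves of survival over days of within-stage exposure with
#' pointwise 95% confidence bands.
#'
#' @param curves Output of [survival_curves()].
#' @param max_day Optionally truncate the x axis (e.g. 20 to focus on the
#'   first days of exposure).
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(curves, max_day = NULL) {
  if (!is.null(max_day)) curves <- curves[curves$day <= max_day, ]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$day, y = .data$survival,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "Days of exposure", y = "Survival probability",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the daily mortality table
#'
#' Bar chart of daily mortality (x10 presentation scale) by annual-cycle
#' stage within each life-cycle class, with 1-SE error bars.
#'
#' @param mort Output of [daily_mortality_table()].
#' @return A ggplot object.
#' @export
plot_daily_mortality <- function(mort) {
  mort <- mort[!is.na(mort$daily_mortality_x10), ]
  mort$stage <- factor(mort$stage, levels = STAGES)
  ggplot2::ggplot(mort, ggplot2::aes(x = .data$stage,
                                     y = .data$daily_mortality_x10,
                                     fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$daily_mortality_x10 - .data$se_x10),
      ymax = .data$daily_mortality_x10 + .data$se_x10
    ), width = 0.25) +
    ggplot2::facet_wrap(~age_class, nrow = 1) +
    ggplot2::labs(x = NULL, y = "Daily mortality rate (x10)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot stage sensitivities with bootstrap error bars
#'
#' @param sens Output of [bootstrap_sensitivities()].
#' @return A ggplot object.
#' @export
plot_sensitivities <- function(sens) {
  sens$stage <- factor(sens$stage, levels = STAGES)
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$stage, y = .data$sensitivity,
                                     fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sensitivity - .data$se,
                                        ymax = .data$sensitivity + .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~age_class, nrow = 1) +
    ggplot2::labs(x = NULL,
                  y = "Sensitivity of population growth rate") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sensitivity chart for a fitted projection model
#'
#' @param object A `fullcycle_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.fullcycle_projection <- function(object, ...) {
  sens <- object$sensitivities
  sens$sensitivity <- sens$sens_mortality
  sens$se <- 0
  plot_sensitivities(sens) +
    ggplot2::labs(y = "Sensitivity of lambda to daily mortality")
}
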