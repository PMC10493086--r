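#' Plot a fitted climate trend
#'
#' Annual values with the fitted regression line.
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trend_fit <- function(object, ...) {
  lab <- paste(stats::na.omit(c(object$season, object$variable)),
               collapse = " ")
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(intercept = object$beta0, slope = object$beta1,
                         colour = "grey30") +
    ggplot2::labs(
      x = "Year", y = object$variable %||% "value",
      title = if (nzchar(lab)) lab else NULL,
      subtitle = sprintf("slope %.4g per year%s (R² = %.2f)",
                         object$beta1, significance_marker(object$p_slope),
                         object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot seasonal climate series with their linear trends
#'
#' One panel per climate variable, points coloured by season, with the
#' fitted trend lines overlaid.
#'
#' @param climate Seasonal climate tibble.
#' @return A ggplot object.
#' @export
plot_climate_trends <- function(climate) {
  climate <- as_tibble(climate)
  check_columns(climate, c("season", "year", climate_vars), "`climate`")
  long <- tidyr::pivot_longer(climate, dplyr::all_of(climate_vars),
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = climate_vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     colour = .data$season)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(cool = "black", warm = "grey55")) +
    ggplot2::labs(x = "Year", y = NULL, colour = "Season") +
    ggplot2::theme_minimal()
}

#' Plot group-level percent coefficients
#'
#' Group means of the percent yield-response coefficients with plus/minus
#' two standard deviation bars, one panel per climate variable.
#'
#' @param summaries Output of [group_summaries()].
#' @return A ggplot object.
#' @export
plot_group_coefficients <- function(summaries) {
  summaries <- as_tibble(summaries)
  check_columns(summaries, c("season", "group", "variable", "mean_pct",
                             "sd_pct"), "`summaries`")
  summaries$variable <- factor(summaries$variable, levels = climate_vars)
  ggplot2::ggplot(
    summaries,
    ggplot2::aes(x = .data$group, y = .data$mean_pct, colour = .data$season)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_pct - 2 * .data$sd_pct,
                   ymax = .data$mean_pct + 2 * .data$sd_pct),
      position = ggplot2::position_dodge(width = 0.4), fatten = 2
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(cool = "black", warm = "grey55")) +
    ggplot2::labs(x = "Cultivar group (period)",
                  y = "Percent coefficient (% per unit)", colour = "Season") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot projected annual actual yield changes
#'
#' Group means of annual actual yield change with plus/minus two standard
#' deviation bars, one panel per climate variable; excluded groups are
#' dropped.
#'
#' @param changes Output of [project_yield_changes()] at group level.
#' @return A ggplot object.
#' @export
plot_yield_changes <- function(changes) {
  changes <- as_tibble(changes)
  check_columns(changes, c("season", "group", "variable",
                           "mean_annual_actual", "sd_annual_actual",
                           "excluded"), "`changes`")
  changes <- changes[!changes$excluded, ]
  changes$variable <- factor(changes$variable, levels = climate_vars)
  ggplot2::ggplot(
    changes,
    ggplot2::aes(x = .data$group, y = .data$mean_annual_actual,
                 colour = .data$season)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_annual_actual - 2 * .data$sd_annual_actual,
                   ymax = .data$mean_annual_actual + 2 * .data$sd_annual_actual),
      position = ggplot2::position_dodge(width = 0.4), fatten = 2
    ) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(cool = "black", warm = "grey55")) +
    ggplot2::labs(x = "Cultivar group (period)",
                  y = "Annual actual yield change (kg/ha per year)",
                  colour = "Season") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
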