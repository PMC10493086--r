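#' Fit the linear time trend of a climate series
#'
#' Ordinary least squares of `value` on `year` (`x = b0 + b1 * t + e`), the
#' standard description of a slowly drifting climate variable. The slope's
#' two-sided p-value comes from the t statistic on `n - 2` degrees of
#' freedom. Years enter uncentred: at this scale centring is numerically
#' irrelevant and the intercept is never interpreted.
#'
#' @param points Data frame with columns `year` and `value` (>= 3 rows, >= 2
#'   distinct years).
#' @param variable,season Optional labels carried into the fit.
#' @return A `trend_fit` object with elements `variable`, `season`, `beta0`,
#'   `beta1` (units per year), `p_slope`, `r2`, `n`, `residual_sd`, `data`.
#' @export
#' @examples
#' fit <- fit_linear_trend(data.frame(year = 1:5, value = 2 + 0.5 * (1:5)))
#' fit$beta1
fit_linear_trend <- function(points, variable = NA_character_,
                             season = NA_character_) {
  points <- as_tibble(points)
  check_columns(points, c("year", "value"), "`points`")
  points <- points[!is.na(points$year) & !is.na(points$value), ]
  if (nrow(points) < 3L) {
    stop_ricedelta(
      sprintf("Trend fit needs at least 3 points, got %d.", nrow(points)),
      "insufficient_data"
    )
  }
  if (length(unique(points$year)) < 2L) {
    stop_ricedelta("All years are identical; the trend is undefined.", "rank")
  }
  fit <- lm(value ~ year, data = points)
  sm <- suppressWarnings(summary(fit))  # exact fits warn about perfect R2
  beta1 <- unname(coef(fit)[["year"]])
  sigma <- sm$sigma
  p_slope <- if (sigma < 1e-12) {
    if (abs(beta1) > 0) 0 else NA_real_
  } else {
    unname(sm$coefficients["year", "Pr(>|t|)"])
  }
  structure(
    list(
      variable = variable, season = season,
      beta0 = unname(coef(fit)[["(Intercept)"]]), beta1 = beta1,
      p_slope = p_slope,
      r2 = if (sigma < 1e-12) 1 else sm$r.squared,
      n = nrow(points), residual_sd = sigma,
      data = points
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$season, x$variable)), collapse = " ")
  cat(sprintf("<trend_fit%s>\n", if (nzchar(lab)) paste0(": ", lab) else ""))
  cat(sprintf("  slope %.5g per year%s (p = %.3g, R2 = %.3f, n = %d)\n",
              x$beta1, significance_marker(x$p_slope), x$p_slope, x$r2, x$n))
  invisible(x)
}

#' Convert a fitted trend into a total change over a period
#'
#' The change of the regression line between its endpoint years:
#' `delta_total = beta1 * (end_year - start_year)`. Note the multiplier is
#' the span in year steps (e.g. 94 for 1925-2019), not the count of calendar
#' years; `n_years = end_year - start_year + 1` is reported alongside.
#'
#' @param fit A `trend_fit`.
#' @param start_year,end_year Period endpoints, `end_year > start_year`.
#' @return A one-row tibble: `variable`, `season`, `start_year`, `end_year`,
#'   `beta1`, `delta_total`, `n_years`.
#' @export
trend_total_change <- function(fit, start_year, end_year) {
  if (!inherits(fit, "trend_fit")) {
    stop_ricedelta("`fit` must be a trend_fit.", "argument")
  }
  if (end_year <= start_year) {
    stop_ricedelta("`end_year` must be after `start_year`.", "argument")
  }
  tibble(
    variable = fit$variable, season = fit$season,
    start_year = as.integer(start_year), end_year = as.integer(end_year),
    beta1 = fit$beta1,
    delta_total = fit$beta1 * (end_year - start_year),
    n_years = as.integer(end_year - start_year + 1L)
  )
}

#' Significance marker for a p-value
#'
#' `"**"` for p < 0.01, `"*"` for 0.01 <= p < 0.05, `"'"` for
#' 0.05 <= p < 0.1, `""` otherwise. Boundary values fall in the weaker
#' class (p = 0.05 gives `"'"`). `NA` gives `""`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Character vector of markers.
#' @export
significance_marker <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_ricedelta("p-values must lie in [0, 1].", "argument")
  }
  out <- character(length(p))
  out[!is.na(p) & p < 0.1] <- "'"
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out
}

#' Fit climate trends for every season and variable
#'
#' Fits [fit_linear_trend()] to each of `T`, `DTR`, `R`, `S` within each
#' season of a seasonal climate table, and appends the trend-implied total
#' change over each requested period (full-record slope times period span).
#'
#' @param climate Seasonal climate tibble (`season`, `year`, `T`, `DTR`,
#'   `R`, `S`).
#' @param periods List of `c(start_year, end_year)` pairs; default is the
#'   full range of the data.
#' @return A tibble with one row per season-variable-period:
#'   `season`, `variable`, `beta0`, `beta1`, `p`, `r2`, `marker`,
#'   `start_year`, `end_year`, `delta_total`.
#' @export
climate_trends <- function(climate, periods = NULL) {
  climate <- as_tibble(climate)
  check_columns(climate, c("season", "year", climate_vars), "`climate`")
  if (is.null(periods)) {
    periods <- list(range(climate$year))
  }
  grid <- tidyr::expand_grid(season = unique(climate$season),
                             variable = climate_vars)
  purrr::pmap(grid, function(season, variable) {
    sub <- climate[climate$season == season, ]
    fit <- fit_linear_trend(
      tibble(year = sub$year, value = sub[[variable]]),
      variable = variable, season = season
    )
    bind_rows(lapply(periods, function(p) {
      tc <- trend_total_change(fit, p[1], p[2])
      tibble(
        season = season, variable = variable,
        beta0 = fit$beta0, beta1 = fit$beta1,
        p = fit$p_slope, r2 = fit$r2,
        marker = significance_marker(fit$p_slope),
        start_year = tc$start_year, end_year = tc$end_year,
        delta_total = tc$delta_total
      )
    }))
  }) |> bind_rows()
}
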