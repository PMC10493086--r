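#' Trend-implied climate change over an analysis period
#'
#' Refits the linear time trend of one climate variable using only the
#' years inside the period (`mode = "period"`, the default) or the full
#' record (`mode = "global"`), and converts the slope into the total change
#' over the period, `delta_total = beta1 * (end_year - start_year)`.
#'
#' @param climate Seasonal climate tibble.
#' @param variable One of `"T"`, `"DTR"`, `"R"`, `"S"`.
#' @param season Season name.
#' @param period `c(start_year, end_year)`.
#' @param mode `"period"` or `"global"` trend window.
#' @return A one-row tibble: `season`, `variable`, `start_year`,
#'   `end_year`, `beta1`, `delta_total`, `n_years`, `mode`.
#' @export
period_delta <- function(climate, variable, season, period,
                         mode = c("period", "global")) {
  mode <- match.arg(mode)
  climate <- as_tibble(climate)
  check_columns(climate, c("season", "year", climate_vars), "`climate`")
  if (!variable %in% climate_vars) {
    stop_ricedelta(sprintf("Unknown climate variable '%s'.", variable),
                   "argument")
  }
  if (length(period) != 2L || period[2] <= period[1]) {
    stop_ricedelta("`period` must be c(start_year, end_year) with end > start.",
                   "argument")
  }
  sub <- climate[climate$season == season, ]
  if (mode == "period") {
    sub <- sub[sub$year >= period[1] & sub$year <= period[2], ]
  }
  if (nrow(sub) < 3L) {
    stop_ricedelta(
      sprintf("Fewer than 3 years of '%s' climate in %d-%d.",
              season, period[1], period[2]),
      "insufficient_data"
    )
  }
  fit <- fit_linear_trend(tibble(year = sub$year, value = sub[[variable]]),
                          variable = variable, season = season)
  out <- trend_total_change(fit, period[1], period[2])
  mutate(out, mode = mode)
}

#' Total relative yield change
#'
#' The percent coefficient times the trend-implied total climate change over
#' the period: `total_relative = pct_beta * delta_total`, in percent of the
#' cultivar's average grain yield.
#'
#' @param pct_beta Percent coefficient (% of average yield per unit).
#' @param delta_total Total change of the climate variable over the period
#'   (variable units), from [period_delta()] or [trend_total_change()].
#' @return Total relative yield change in percent (vectorized).
#' @export
total_relative_change <- function(pct_beta, delta_total) {
  if (!is.numeric(pct_beta) || !is.numeric(delta_total)) {
    stop_ricedelta("`pct_beta` and `delta_total` must be numeric.", "argument")
  }
  pct_beta * delta_total
}

#' Annual actual yield change
#'
#' The absolute coefficient times the total climate change over the period,
#' divided by the number of calendar years in the period:
#' `annual_actual = beta * delta_total / n_years`, in kg/ha per year.
#'
#' @param beta Absolute coefficient (kg/ha per unit).
#' @param delta_total Total change of the climate variable (variable units).
#' @param n_years Number of calendar years in the period
#'   (`end - start + 1`), at least 1.
#' @return Annual actual yield change in kg/ha per year (vectorized).
#' @export
annual_actual_change <- function(beta, delta_total, n_years) {
  if (any(n_years < 1)) {
    stop_ricedelta("`n_years` must be at least 1.", "argument")
  }
  beta * delta_total / n_years
}

#' Project yield changes per group and period
#'
#' Combines cultivar-level regression coefficients with the trend-implied
#' climate change of each group's period into total relative (%) and annual
#' actual (kg/ha per year) yield changes, then averages over group members
#' (mean and sample SD). Groups flagged `excluded` are carried through with
#' their flag so downstream consumers can drop them.
#'
#' @param results Cultivar-level regression results
#'   ([regress_cultivars()] output: `season`, `cultivar`, `avg_yield`,
#'   `beta_*`, `pct_*`).
#' @param climate Seasonal climate tibble.
#' @param groups Group membership tibble as from [build_groups()].
#' @param mode Trend window for the climate delta, `"period"` (default) or
#'   `"global"`; see [period_delta()].
#' @param level `"group"` (default) for group mean/SD rows, `"cultivar"`
#'   for the underlying per-cultivar rows.
#' @return For `level = "group"`: a tibble `season`, `group`,
#'   `start_year`, `end_year`, `variable`, `delta_total`,
#'   `mean_total_relative`, `sd_total_relative`, `mean_annual_actual`,
#'   `sd_annual_actual`, `n_years`, `n_members`, `excluded`, `mode`. For
#'   `level = "cultivar"`: one row per member with `avg_yield`,
#'   `total_relative` and `annual_actual`.
#' @export
project_yield_changes <- function(results, climate,
                                  groups = taichung_groups(),
                                  mode = c("period", "global"),
                                  level = c("group", "cultivar")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  results <- as_tibble(results)
  check_columns(results,
                c("season", "cultivar", "avg_yield",
                  paste0("beta_", climate_vars), paste0("pct_", climate_vars)),
                "`results`")
  groups <- as_tibble(groups)
  keys <- dplyr::distinct(groups, .data$season, .data$group,
                          .data$start_year, .data$end_year, .data$excluded)
  detail <- purrr::pmap(keys, function(season, group, start_year, end_year,
                                       excluded) {
    member_ids <- groups$cultivar[groups$season == season &
                                    groups$group == group]
    members <- results[results$season == season &
                         results$cultivar %in% member_ids, ]
    if (nrow(members) == 0L) return(NULL)
    purrr::map(climate_vars, function(v) {
      pd <- period_delta(climate, v, season, c(start_year, end_year),
                         mode = mode)
      tibble(
        season = season, group = group,
        start_year = start_year, end_year = end_year,
        variable = v, cultivar = members$cultivar,
        avg_yield = members$avg_yield,
        delta_total = pd$delta_total,
        total_relative = total_relative_change(
          members[[paste0("pct_", v)]], pd$delta_total
        ),
        annual_actual = annual_actual_change(
          members[[paste0("beta_", v)]], pd$delta_total, pd$n_years
        ),
        n_years = pd$n_years, excluded = excluded, mode = mode
      )
    }) |> bind_rows()
  }) |> bind_rows()
  if (level == "cultivar") {
    return(detail)
  }
  detail |>
    group_by(.data$season, .data$group, .data$start_year, .data$end_year,
             .data$variable, .data$delta_total, .data$n_years,
             .data$excluded, .data$mode) |>
    summarise(
      mean_total_relative = mean(.data$total_relative),
      sd_total_relative = if (n() < 2L) NA_real_ else sd(.data$total_relative),
      mean_annual_actual = mean(.data$annual_actual),
      sd_annual_actual = if (n() < 2L) NA_real_ else sd(.data$annual_actual),
      n_members = n(),
      .groups = "drop"
    ) |>
    select("season", "group", "start_year", "end_year", "variable",
           "delta_total", "mean_total_relative", "sd_total_relative",
           "mean_annual_actual", "sd_annual_actual", "n_years",
           "n_members", "excluded", "mode") |>
    arrange(.data$season, .data$start_year, .data$group, .data$variable)
}
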