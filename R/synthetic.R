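#' Define a synthetic daily-weather scenario
#'
#' A weather scenario describes a stochastic generator of daily station
#' weather for a subtropical lowland site: a sinusoidal annual temperature
#' cycle with an AR(1) day-to-day anomaly, linear long-term trends applied
#' separately to daily minimum and maximum temperature (so warming can be
#' concentrated in the nights, shrinking the diurnal temperature range), a
#' Bernoulli-Gamma daily rainfall mixture whose Gamma scale drifts to impose
#' a rainfall trend, and sunshine duration driven by day length with a
#' penalty on rain days. A fraction of whole days is removed at random to
#' emulate missing station records.
#'
#' The defaults emulate a 95-year (1925-2019) record from central-western
#' Taiwan: cool-season (Jan 20 - Jun 23) mean temperature near 21.7 degC,
#' minimum-temperature warming of about 1.5 degC over the record against
#' about 0.3 degC for maximum temperature, declining rainfall and sunshine,
#' and 2.65% of days missing.
#'
#' @param start_year,end_year First and last calendar year generated.
#' @param baseline_tavg Annual-mean daily average temperature in the first
#'   year (degC).
#' @param seasonal_amplitude Half-range of the annual temperature cycle
#'   (degC); the cycle peaks in mid July.
#' @param baseline_dtr Mean diurnal temperature range in the first year
#'   (degC).
#' @param trend_tmin,trend_tmax Linear trends of daily minimum and maximum
#'   temperature (degC per year).
#' @param ar1_coeff Lag-1 autocorrelation of the daily temperature anomaly,
#'   in `[0, 1)`.
#' @param anomaly_sd Stationary standard deviation of the daily temperature
#'   anomaly (degC); also scales the DTR and sunshine noise. `0` gives a
#'   fully deterministic series.
#' @param rain_prob Probability that a day is wet, in `[0, 1]`.
#' @param rain_gamma_shape,rain_gamma_scale Gamma parameters of wet-day
#'   rainfall (scale in mm).
#' @param rain_trend Trend of annual total rainfall (mm per year), imposed
#'   by drifting the Gamma scale.
#' @param sunshine_max Clear-day sunshine duration at unit day-length
#'   fraction (h).
#' @param sunshine_rain_penalty Sunshine reduction on wet days (h).
#' @param sunshine_trend Trend of daily sunshine duration (h per day per
#'   year).
#' @param missing_rate Fraction of whole days whose record is missing, in
#'   `[0, 1)`.
#' @param seed Integer seed; identical scenarios generate identical data.
#'
#' @return An object of class `weather_scenario`.
#' @seealso [synth_weather()]
#' @export
#' @examples
#' sc <- weather_scenario(start_year = 2000, end_year = 2004)
#' head(synth_weather(sc))
weather_scenario <- function(start_year = 1925, end_year = 2019,
                             baseline_tavg = 22, seasonal_amplitude = 7,
                             baseline_dtr = 8.6,
                             trend_tmin = 0.016, trend_tmax = 0.003,
                             ar1_coeff = 0.9, anomaly_sd = 1.8,
                             rain_prob = 0.32, rain_gamma_shape = 0.7,
                             rain_gamma_scale = 25, rain_trend = -6,
                             sunshine_max = 14, sunshine_rain_penalty = 3.5,
                             sunshine_trend = -0.012,
                             missing_rate = 0.0265, seed = 1L) {
  check_number(start_year, "start_year")
  check_number(end_year, "end_year", min = start_year)
  check_number(seasonal_amplitude, "seasonal_amplitude", min = 0)
  check_number(baseline_dtr, "baseline_dtr", min = 0)
  check_number(ar1_coeff, "ar1_coeff", min = 0, max = 1, allow_max = FALSE)
  check_number(anomaly_sd, "anomaly_sd", min = 0)
  check_number(rain_prob, "rain_prob", min = 0, max = 1)
  check_number(rain_gamma_shape, "rain_gamma_shape", min = 0, allow_min = FALSE)
  check_number(rain_gamma_scale, "rain_gamma_scale", min = 0, allow_min = FALSE)
  check_number(sunshine_max, "sunshine_max", min = 0, max = 24)
  check_number(sunshine_rain_penalty, "sunshine_rain_penalty", min = 0)
  check_number(missing_rate, "missing_rate", min = 0, max = 1, allow_max = FALSE)
  check_number(seed, "seed")
  structure(
    list(
      start_year = as.integer(start_year), end_year = as.integer(end_year),
      baseline_tavg = baseline_tavg, seasonal_amplitude = seasonal_amplitude,
      baseline_dtr = baseline_dtr,
      trend_tmin = trend_tmin, trend_tmax = trend_tmax,
      ar1_coeff = ar1_coeff, anomaly_sd = anomaly_sd,
      rain_prob = rain_prob, rain_gamma_shape = rain_gamma_shape,
      rain_gamma_scale = rain_gamma_scale, rain_trend = rain_trend,
      sunshine_max = sunshine_max,
      sunshine_rain_penalty = sunshine_rain_penalty,
      sunshine_trend = sunshine_trend,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "weather_scenario"
  )
}

#' Generate a synthetic daily weather series
#'
#' Draws one record per calendar day of the scenario's year range (leap days
#' included). Missing days carry `NA` in every weather variable; they are
#' flagged, never zero-filled. Generated records always satisfy
#' `tmin <= tavg <= tmax`, `rain >= 0` and `0 <= sunshine <= 24`.
#'
#' @param scenario A [weather_scenario()].
#' @return A tibble with columns `date`, `tavg`, `tmin`, `tmax`, `rain`,
#'   `sunshine`.
#' @export
synth_weather <- function(scenario) {
  if (!inherits(scenario, "weather_scenario")) {
    stop_ricedelta("`scenario` must be created by weather_scenario().", "config")
  }
  dates <- seq(as.Date(sprintf("%d-01-01", scenario$start_year)),
               as.Date(sprintf("%d-12-31", scenario$end_year)), by = "day")
  n <- length(dates)
  year <- as.integer(format(dates, "%Y"))
  doy <- as.POSIXlt(dates)$yday + 1
  t_idx <- year - scenario$start_year

  seasonal <- scenario$baseline_tavg +
    scenario$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  trend_avg <- 0.5 * (scenario$trend_tmin + scenario$trend_tmax)

  withr::with_seed(scenario$seed, {
    innov_sd <- scenario$anomaly_sd * sqrt(1 - scenario$ar1_coeff^2)
    anom <- as.numeric(stats::filter(
      rnorm(n, 0, innov_sd), scenario$ar1_coeff, method = "recursive"
    ))
    dtr_noise <- rnorm(n, 0, 0.5 * scenario$anomaly_sd)
    wet <- runif(n) < scenario$rain_prob
    daily_rain_mean <- scenario$rain_prob * scenario$rain_gamma_shape *
      scenario$rain_gamma_scale
    if (daily_rain_mean > 0) {
      scale_y <- scenario$rain_gamma_scale *
        (1 + scenario$rain_trend * t_idx / (365.25 * daily_rain_mean))
      amount <- rgamma(n, shape = scenario$rain_gamma_shape,
                       scale = pmax(scale_y, 1e-6))
    } else {
      amount <- numeric(n)
    }
    sun_noise <- rnorm(n, 0, 0.5 * scenario$anomaly_sd)
    miss <- runif(n) < scenario$missing_rate
  })

  tavg <- seasonal + trend_avg * t_idx + anom
  dtr <- pmax(scenario$baseline_dtr +
                (scenario$trend_tmax - scenario$trend_tmin) * t_idx +
                dtr_noise, 0)
  rain <- ifelse(wet, amount, 0)
  daylight <- 0.5 - 0.07 * cos(2 * pi * (doy - 172) / 365.25)
  sunshine <- scenario$sunshine_max * daylight +
    scenario$sunshine_trend * t_idx -
    scenario$sunshine_rain_penalty * wet + sun_noise
  sunshine <- pmin(pmax(sunshine, 0), 24)

  out <- tibble(
    date = dates,
    tavg = tavg, tmin = tavg - dtr / 2, tmax = tavg + dtr / 2,
    rain = rain, sunshine = sunshine
  )
  out[miss, c("tavg", "tmin", "tmax", "rain", "sunshine")] <- NA_real_
  out
}

#' Define a synthetic cultivar-yield scenario
#'
#' Each cultivar's annual grain yield is linear in its season's climate plus
#' a technology trend and Gaussian noise:
#' `Y = intercept + tech_trend * (year - first_year) + beta_T * T +
#' beta_DTR * DTR + beta_R * R + beta_S * S + e`, `e ~ N(0, noise_sd)`.
#' Years listed in `gap_years` produce no record at all (the trials were not
#' run), never a zero yield.
#'
#' @param cultivars A data frame with one row per cultivar and columns `id`,
#'   `season` (`"cool"` or `"warm"`), `first_year`, `last_year`, `intercept`
#'   (kg/ha), `tech_trend` (kg/ha per year), `beta_T`, `beta_DTR` (kg/ha per
#'   degC), `beta_R` (kg/ha per mm), `beta_S` (kg/ha per h), `noise_sd`
#'   (kg/ha, `>= 0`).
#' @param gap_years Integer vector of years with no experiment.
#' @param seed Integer seed.
#' @return An object of class `yield_scenario`.
#' @seealso [synth_yields()]
#' @export
yield_scenario <- function(cultivars, gap_years = integer(), seed = 1L) {
  cultivars <- as_tibble(cultivars)
  check_columns(cultivars, c("id", "season", "first_year", "last_year",
                             "intercept", "tech_trend", "beta_T", "beta_DTR",
                             "beta_R", "beta_S", "noise_sd"),
                "`cultivars`")
  if (any(cultivars$last_year < cultivars$first_year)) {
    stop_ricedelta("Each cultivar needs last_year >= first_year.", "config")
  }
  if (any(cultivars$noise_sd < 0)) {
    stop_ricedelta("`noise_sd` must be non-negative.", "config")
  }
  if (!all(cultivars$season %in% c("cool", "warm"))) {
    stop_ricedelta("Cultivar seasons must be 'cool' or 'warm'.", "config")
  }
  structure(
    list(cultivars = cultivars, gap_years = as.integer(gap_years),
         seed = as.integer(seed)),
    class = "yield_scenario"
  )
}

#' Generate synthetic cultivar yield series from seasonal climate
#'
#' @param scenario A [yield_scenario()].
#' @param climate Seasonal climate table with columns `season`, `year`, `T`,
#'   `DTR`, `R`, `S` (for example from [seasonal_climate()]); it must cover
#'   every cultivar's cultivation span outside the gap years.
#' @return A tibble with columns `cultivar`, `season`, `year`, `yield`.
#' @export
synth_yields <- function(scenario, climate) {
  if (!inherits(scenario, "yield_scenario")) {
    stop_ricedelta("`scenario` must be created by yield_scenario().", "config")
  }
  climate <- as_tibble(climate)
  check_columns(climate, c("season", "year", climate_vars), "`climate`")
  withr::with_seed(scenario$seed, {
    rows <- purrr::pmap(scenario$cultivars, function(id, season, first_year,
                                                    last_year, intercept,
                                                    tech_trend, beta_T,
                                                    beta_DTR, beta_R, beta_S,
                                                    noise_sd, ...) {
      years <- setdiff(seq(first_year, last_year), scenario$gap_years)
      cli <- climate[climate$season == season & climate$year %in% years, ]
      missing_years <- setdiff(years, cli$year)
      if (length(missing_years) > 0L) {
        stop_ricedelta(
          sprintf(
            "Climate series does not cover cultivar '%s' (%s season) in year%s %s.",
            id, season, if (length(missing_years) > 1L) "s" else "",
            paste(missing_years, collapse = ", ")
          ),
          "coverage"
        )
      }
      cli <- cli[order(cli$year), ]
      yield <- intercept + tech_trend * (cli$year - first_year) +
        beta_T * cli$T + beta_DTR * cli$DTR + beta_R * cli$R +
        beta_S * cli$S + rnorm(nrow(cli), 0, noise_sd)
      tibble(cultivar = id, season = season, year = cli$year, yield = yield)
    })
  })
  dplyr::bind_rows(rows) |> arrange(.data$season, .data$cultivar, .data$year)
}
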