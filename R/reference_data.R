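#' Cultivation spans of the 14 Taichung trial cultivars
#'
#' Cultivation spans of the japonica (Pon-Lai) and indica rice cultivars
#' grown in the 1925-2019 long-term field trial at the Taichung district
#' agricultural research station, by cropping season. Cultivars grown over
#' interrupted spans (the trials paused in 1948-1951 and 1985-1995, and for
#' shorter stretches around 1945 and 2013-2016) have one row per contiguous
#' span.
#'
#' @return A tibble with columns `cultivar`, `season`, `first_year`,
#'   `last_year`.
#' @export
taichung_cultivars <- function() {
  spans <- function(cultivar, season, ...) {
    sp <- list(...)
    tibble(
      cultivar = cultivar, season = season,
      first_year = as.integer(vapply(sp, `[[`, numeric(1), 1)),
      last_year = as.integer(vapply(sp, `[[`, numeric(1), 2))
    )
  }
  bind_rows(
    # cool cropping season
    spans("NM", "cool", c(1925, 1931)),
    spans("TCS2", "cool", c(1925, 1932)),
    spans("BK", "cool", c(1925, 1944)),
    spans("TCS6", "cool", c(1933, 1944)),
    spans("WG", "cool", c(1925, 1947), c(1952, 1976)),
    spans("BMF", "cool", c(1945, 1947), c(1952, 1976)),
    spans("TC65", "cool", c(1930, 1947), c(1952, 1983)),
    spans("TC150", "cool", c(1945, 1947), c(1952, 1983)),
    spans("TCI1", "cool", c(1964, 1983)),
    spans("TCI3", "cool", c(1977, 1983)),
    spans("TA67", "cool", c(1996, 2013), c(2017, 2019)),
    spans("TC189", "cool", c(1996, 2013), c(2017, 2019)),
    spans("TCI10", "cool", c(1996, 2013), c(2017, 2019)),
    spans("TJ9", "cool", c(2000, 2013), c(2017, 2019)),
    # warm cropping season
    spans("NM", "warm", c(1925, 1931)),
    spans("TCS2", "warm", c(1925, 1944)),
    spans("JG", "warm", c(1925, 1944)),
    spans("NY", "warm", c(1925, 1944)),
    spans("SJ", "warm", c(1946, 1946), c(1952, 1976)),
    spans("SL", "warm", c(1946, 1946), c(1952, 1976)),
    spans("TC65", "warm", c(1930, 1944), c(1946, 1946), c(1952, 1983)),
    spans("TC150", "warm", c(1946, 1946), c(1952, 1983)),
    spans("TCI2", "warm", c(1977, 1983)),
    spans("TCI3", "warm", c(1977, 1983)),
    spans("TA67", "warm", c(1996, 2012), c(2016, 2019)),
    spans("TC189", "warm", c(1996, 2012), c(2016, 2019)),
    spans("TCI10", "warm", c(1996, 2012), c(2016, 2019)),
    spans("TJ9", "warm", c(2000, 2012), c(2016, 2019))
  )
}

#' Published percent yield-response coefficients of the Taichung cultivars
#'
#' The published cultivar-level percent regression coefficients (percent of
#' average grain yield per unit of climate change) of rice yield first
#' differences on first differences of seasonal average temperature (`T`,
#' per degC), diurnal temperature range (`DTR`, per degC), rainfall (`R`,
#' per mm) and sunshine duration (`S`, per h), for the 14 cultivars of the
#' 1925-2019 Taichung long-term field trial. These serve as worked-example
#' inputs for [summarize_group()] and as reference values for regression
#' outputs when the deposited station data are available.
#'
#' @return A tibble with columns `season`, `cultivar`, `pct_T`, `pct_DTR`,
#'   `pct_R`, `pct_S`.
#' @export
taichung_coefficients <- function() {
  cool <- tibble(
    season = "cool",
    cultivar = c("NM", "TCS2", "BK", "TCS6", "WG", "BMF", "TC65", "TC150",
                 "TCI1", "TCI3", "TA67", "TC189", "TCI10", "TJ9"),
    pct_T = c(37.94, 71.82, 7.28, -8.00, 3.29, 0.00, 2.98, -1.30,
              0.61, -13.08, -2.32, -6.29, -3.88, -11.19),
    pct_DTR = c(-61.38, -69.51, -3.99, -40.92, -2.14, 2.68, -5.90, -8.01,
                -10.64, -22.99, 24.94, 31.44, 23.83, 48.61),
    pct_R = c(-2.12, -3.80, -2.13, -11.42, 0.09, -1.13, -1.03, -0.68,
              -1.33, 1.56, 0.65, 1.47, 0.14, 0.92),
    pct_S = c(-0.35, -5.04, -6.61, -2.36, 0.80, 4.21, 1.25, 7.13,
              5.27, 8.82, -9.46, -7.99, -3.55, -9.24)
  )
  warm <- tibble(
    season = "warm",
    cultivar = c("NM", "TCS2", "JG", "NY", "SJ", "SL", "TC65", "TC150",
                 "TCI2", "TCI3", "TA67", "TC189", "TCI10", "TJ9"),
    pct_T = c(-16.28, -15.55, -5.22, -4.57, -4.30, -8.85, -0.03, -6.57,
              -67.40, -46.75, 13.96, -5.93, -0.98, -10.02),
    pct_DTR = c(-9.45, -2.51, 1.50, -1.95, -0.73, -7.99, 2.77, 0.27,
                34.51, -64.65, -3.49, -8.56, -13.86, -8.33),
    pct_R = c(-4.00, -2.69, -1.44, -1.47, -0.06, -3.71, -0.35, -0.81,
              -9.34, -1.41, -0.52, -3.21, -3.45, -4.09),
    pct_S = c(-29.87, -11.80, -9.95, -9.07, 4.66, 1.13, 2.80, 3.64,
              -13.88, 58.85, -5.96, -1.57, -3.91, -8.83)
  )
  bind_rows(cool, warm)
}

#' Cultivar grouping of the Taichung trial
#'
#' The grouping of cultivars with overlapping cultivation periods used to
#' summarize coefficients over eras of the 1925-2019 Taichung trial: four
#' groups per season over 1925-1944, 1945-1983, 1977-1983 and 1996-2019.
#' The 1977-1983 group has only two members, spans only seven years and
#' lies inside the 1945-1983 period, so it is flagged `excluded` and is
#' dropped from projection summaries (while still being computed and
#' written).
#'
#' @return A tibble with columns `season`, `group`, `start_year`,
#'   `end_year`, `cultivar`, `excluded` (one row per member).
#' @export
taichung_groups <- function() {
  g <- function(season, group, start, end, members, excluded = FALSE) {
    tibble(season = season, group = group,
           start_year = as.integer(start), end_year = as.integer(end),
           cultivar = members, excluded = excluded)
  }
  bind_rows(
    g("cool", "1925-1944", 1925, 1944, c("NM", "TCS2", "BK", "TCS6")),
    g("cool", "1945-1983", 1945, 1983, c("WG", "BMF", "TC65", "TC150")),
    g("cool", "1977-1983", 1977, 1983, c("TCI1", "TCI3"), excluded = TRUE),
    g("cool", "1996-2019", 1996, 2019, c("TA67", "TC189", "TCI10", "TJ9")),
    g("warm", "1925-1944", 1925, 1944, c("NM", "TCS2", "JG", "NY")),
    g("warm", "1945-1983", 1945, 1983, c("SJ", "SL", "TC65", "TC150")),
    g("warm", "1977-1983", 1977, 1983, c("TCI2", "TCI3"), excluded = TRUE),
    g("warm", "1996-2019", 1996, 2019, c("TA67", "TC189", "TCI10", "TJ9"))
  )
}

#' Years in which the Taichung trials were not conducted
#'
#' No yields exist for any cultivar in 1948-1951, 1985-1995, 2014 and 2015
#' (plus season-specific interruptions captured by the cultivation spans).
#'
#' @return An integer vector of years.
#' @export
taichung_gap_years <- function() {
  as.integer(c(1948:1951, 1985:1995, 2014, 2015))
}
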