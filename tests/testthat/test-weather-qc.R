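# Quiet series: Gaussian temperature variability only, no rain process, so
# the 4-SD outlier screen never fires on the clean data.
clean_weather_3y <- function() {
  synth_weather(weather_scenario(start_year = 1929, end_year = 1931,
                                 anomaly_sd = 1, ar1_coeff = 0.4,
                                 rain_prob = 0, missing_rate = 0, seed = 2))
}

rainy_weather_3y <- function() {
  synth_weather(weather_scenario(start_year = 1929, end_year = 1931,
                                 missing_rate = 0, seed = 2))
}

test_that("a clean series passes QC untouched with zero counts", {
  w <- synth_weather(weather_scenario(start_year = 2000, end_year = 2002,
                                      anomaly_sd = 0, rain_prob = 0,
                                      missing_rate = 0))
  qc <- impute_weather(w)
  expect_identical(qc$weather, w)
  expect_equal(qc$report$n_missing_cells, 0L)
  expect_equal(qc$report$n_missing_replaced, 0L)
  expect_equal(qc$report$n_outliers_replaced, 0L)
  expect_equal(qc$report$n_unresolved, 0L)
  expect_equal(qc$report$fraction_missing_days, 0)
})

test_that("a missing value is replaced by the mean of adjacent years' same day", {
  w <- clean_weather_3y()
  i <- which(w$date == as.Date("1930-03-05"))
  w$tavg[which(w$date == as.Date("1929-03-05"))] <- 18
  w$tavg[which(w$date == as.Date("1931-03-05"))] <- 20
  w$tavg[i] <- NA
  qc <- impute_weather(w)
  expect_equal(qc$weather$tavg[i], 19)
  expect_equal(qc$report$n_missing_replaced, 1L)
  log <- qc$report$log
  expect_equal(log$rule[log$date == as.Date("1930-03-05")],
               "missing_neighbour_mean")
})

test_that("a single usable neighbour year is used alone at series ends", {
  w <- clean_weather_3y()
  i <- which(w$date == as.Date("1929-06-10"))  # first year: no preceding year
  w$tavg[which(w$date == as.Date("1930-06-10"))] <- 23.5
  w$tavg[i] <- NA
  qc <- impute_weather(w)
  expect_equal(qc$weather$tavg[i], 23.5)
  expect_equal(qc$report$log$rule[qc$report$log$date == w$date[i]],
               "missing_single_neighbour")
})

test_that("an injected spike is flagged as outlier and neighbour-imputed", {
  w <- clean_weather_3y()
  i <- which(w$date == as.Date("1930-04-15"))
  prev <- w$tavg[which(w$date == as.Date("1929-04-15"))]
  nxt <- w$tavg[which(w$date == as.Date("1931-04-15"))]
  w$tavg[i] <- w$tavg[i] + 40  # far beyond 6 climatological SDs
  qc <- impute_weather(w, outlier_z = 6)
  expect_equal(qc$report$n_outliers_replaced, 1L)
  expect_equal(qc$weather$tavg[i], mean(c(prev, nxt)))
})

test_that("doubly-missing neighbours leave the cell absent unless climatology fallback", {
  w <- clean_weather_3y()
  days <- as.Date(c("1929-05-01", "1930-05-01", "1931-05-01"))
  w$tavg[w$date %in% days] <- NA
  strict <- impute_weather(w, fallback = "none")
  i <- which(w$date == days[2])
  expect_true(is.na(strict$weather$tavg[i]))
  expect_equal(strict$report$n_unresolved, 3L)
  filled <- impute_weather(w, fallback = "climatology")
  expect_false(anyNA(filled$weather$tavg))
  expect_true("climatology" %in% filled$report$log$rule)
})

test_that("imputation is idempotent", {
  w <- clean_weather_3y()
  w$tavg[which(w$date == as.Date("1930-03-05"))] <- NA
  w$sunshine[which(w$date == as.Date("1930-09-20"))] <- NA
  once <- impute_weather(w)
  twice <- impute_weather(once$weather)
  expect_equal(twice$weather, once$weather)
  expect_equal(twice$report$n_missing_replaced, 0L)
})

test_that("seasonal aggregation matches hand-computed sums and means", {
  season <- list(name = "toy", start = "01-01", end = "01-03")
  w <- tibble::tibble(
    date = as.Date(c("2000-01-01", "2000-01-02", "2000-01-03")),
    tavg = c(18, 20, 22), tmin = c(12, 14, 16), tmax = c(24, 26, 28),
    rain = c(0, 10, 0), sunshine = c(5, 0, 7)
  )
  rec <- aggregate_season(w, season, 2000)
  expect_equal(rec$T, 20)
  expect_equal(rec$DTR, 12)  # mean of tmax - tmin = (12 + 12 + 12)/3
  expect_equal(rec$R, 10)
  expect_equal(rec$S, 12)
  expect_equal(rec$n_days, 3L)

  const <- w
  const$tavg <- 20; const$tmin <- 15; const$tmax <- 25
  const$rain <- 2; const$sunshine <- 6
  rec2 <- aggregate_season(const, season, 2000)
  expect_equal(unlist(rec2[c("T", "DTR", "R", "S")]),
               c(T = 20, DTR = 10, R = 6, S = 18))
})

test_that("aggregation errors name unresolved or absent days in the window", {
  w <- clean_weather_3y()
  season <- list(name = "cool", start = "01-20", end = "06-23")
  w$rain[w$date == as.Date("1930-02-10")] <- NA
  expect_error(aggregate_season(w, season, 1930),
               regexp = "1930-02-10", class = "ricedelta_aggregation")
  w2 <- clean_weather_3y()
  w2 <- w2[w2$date != as.Date("1930-03-01"), ]
  expect_error(aggregate_season(w2, season, 1930),
               regexp = "1930-03-01", class = "ricedelta_aggregation")
})

test_that("rainfall aggregation is additive over a partition of the window", {
  w <- rainy_weather_3y()
  full <- aggregate_season(w, list(name = "x", start = "02-01", end = "02-28"),
                           1930)
  a <- aggregate_season(w, list(name = "x", start = "02-01", end = "02-14"),
                        1930)
  b <- aggregate_season(w, list(name = "x", start = "02-15", end = "02-28"),
                        1930)
  expect_equal(a$R + b$R, full$R)
  expect_equal(a$S + b$S, full$S)
  # permutation invariance within the window
  shuffled <- w[sample(nrow(w)), ]
  expect_equal(
    aggregate_season(shuffled, list(name = "x", start = "02-01", end = "02-28"),
                     1930),
    full
  )
})

test_that("leap years lengthen the date-anchored cool window by one day", {
  w <- synth_weather(weather_scenario(start_year = 1999, end_year = 2000,
                                      missing_rate = 0, seed = 4))
  cli <- seasonal_climate(w)
  cool <- cli[cli$season == "cool", ]
  expect_equal(cool$n_days[cool$year == 1999], 155L)
  expect_equal(cool$n_days[cool$year == 2000], 156L)  # Feb 29 included
})

test_that("n_imputed counts logged replacements inside the window", {
  w <- clean_weather_3y()
  w$tavg[w$date == as.Date("1930-03-05")] <- NA   # inside cool window
  w$tavg[w$date == as.Date("1930-12-25")] <- NA   # outside any window
  qc <- impute_weather(w)
  cli <- seasonal_climate(qc$weather, report = qc$report)
  cool_1930 <- cli[cli$season == "cool" & cli$year == 1930, ]
  expect_equal(cool_1930$n_imputed, 1L)
})
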