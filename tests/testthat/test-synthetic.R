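test_that("noise-free scenario is a deterministic sinusoid with no rain or gaps", {
  sc <- weather_scenario(start_year = 2000, end_year = 2002,
                         anomaly_sd = 0, rain_prob = 0, missing_rate = 0)
  w <- synth_weather(sc)
  expect_equal(nrow(w), as.integer(as.Date("2003-01-01") - as.Date("2000-01-01")))
  expect_false(anyNA(w))
  expect_true(all(w$rain == 0))
  cli <- seasonal_climate(w)
  expect_true(all(cli$R == 0))
  # pure seasonal cycle plus linear trend: same calendar day one year apart
  # differs exactly by the trend step (compare non-leap-shifted days)
  jan1 <- w$tavg[format(w$date, "%m-%d") == "01-01"]
  steps <- diff(jan1)
  expect_equal(steps, rep(0.5 * (sc$trend_tmin + sc$trend_tmax), 2),
               tolerance = 1e-6)
})

test_that("generated records respect physical invariants", {
  w <- synth_weather(weather_scenario(start_year = 1990, end_year = 1999,
                                      seed = 3))
  ok <- !is.na(w$tavg)
  expect_true(all(w$tmin[ok] <= w$tavg[ok]))
  expect_true(all(w$tavg[ok] <= w$tmax[ok]))
  expect_true(all(w$rain[ok] >= 0))
  expect_true(all(w$sunshine[ok] >= 0 & w$sunshine[ok] <= 24))
})

test_that("same seed reproduces a byte-identical weather CSV", {
  sc <- weather_scenario(start_year = 2000, end_year = 2004, seed = 99)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_weather_csv(synth_weather(sc), p1)
  write_weather_csv(synth_weather(sc), p2)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed does not
  sc2 <- weather_scenario(start_year = 2000, end_year = 2004, seed = 100)
  expect_false(identical(synth_weather(sc2), synth_weather(sc)))
})

test_that("fitted seasonal trends recover the implied generator slopes", {
  # warming concentrated in tmin: tavg slope = (trend_tmin + trend_tmax)/2,
  # DTR slope = trend_tmax - trend_tmin
  sc <- weather_scenario(start_year = 1925, end_year = 2019,
                         trend_tmin = 0.016, trend_tmax = 0.003,
                         anomaly_sd = 0, rain_prob = 0, missing_rate = 0)
  cli <- seasonal_climate(synth_weather(sc))
  trends <- climate_trends(cli)
  t_cool <- trends[trends$season == "cool" & trends$variable == "T", ]
  expect_equal(t_cool$beta1, 0.0095, tolerance = 1e-3)
  expect_equal(t_cool$delta_total, 0.0095 * 94, tolerance = 0.02)
  dtr <- trends[trends$season == "cool" & trends$variable == "DTR", ]
  expect_equal(dtr$beta1, -0.013, tolerance = 1e-3)
  expect_lt(dtr$delta_total, 0)
})

test_that("missing days appear at the configured rate and are flagged, not zero", {
  sc <- weather_scenario(start_year = 1925, end_year = 2019,
                         missing_rate = 0.0265, seed = 5)
  w <- synth_weather(sc)
  frac <- mean(is.na(w$tavg))
  # binomial expectation: within 0.5 percentage points at this series length
  expect_lt(abs(frac - 0.0265), 0.005)
  miss <- is.na(w$tavg)
  expect_true(all(is.na(w$rain[miss])))
})

test_that("invalid scenario parameters are rejected as configuration errors", {
  expect_error(weather_scenario(rain_prob = 1.2), class = "ricedelta_config")
  expect_error(weather_scenario(missing_rate = 1), class = "ricedelta_config")
  expect_error(weather_scenario(anomaly_sd = -1), class = "ricedelta_config")
  expect_error(weather_scenario(start_year = 2000, end_year = 1999),
               class = "ricedelta_config")
})

test_that("noise-free yields follow the generating line and its differences", {
  cli <- make_climate(2000, 2009)
  cult <- known_cultivar(2000, 2009, beta_T = 0, beta_DTR = 0, beta_R = 0,
                         beta_S = 0, tech_trend = 10)
  y <- synth_yields(yield_scenario(cult), cli)
  expect_equal(nrow(y), 10L)
  fd <- first_difference(tibble::tibble(year = y$year, value = y$yield))
  expect_equal(fd$delta, rep(10, 9))
})

test_that("gap years produce absent records, never zeros", {
  cli <- make_climate(2000, 2009)
  y <- synth_yields(
    yield_scenario(known_cultivar(2000, 2009), gap_years = c(2003L, 2004L)),
    cli
  )
  expect_false(any(y$year %in% c(2003, 2004)))
  expect_equal(nrow(y), 8L)
  expect_true(all(y$yield > 0))
})

test_that("insufficient climate coverage raises a coverage error", {
  cli <- make_climate(2000, 2005)
  expect_error(
    synth_yields(yield_scenario(known_cultivar(2000, 2009)), cli),
    class = "ricedelta_coverage"
  )
})

test_that("yield generation is seed-reproducible", {
  cli <- make_climate(2000, 2009)
  sc <- yield_scenario(known_cultivar(2000, 2009, noise_sd = 300), seed = 8)
  expect_identical(synth_yields(sc, cli), synth_yields(sc, cli))
})

test_that("fixture registry builds its fixtures and rejects unknown names", {
  expect_error(make_fixture("no-such-fixture"), class = "ricedelta_lookup")

  dir <- withr::local_tempdir()
  paths <- make_fixture("toy-linear", dir)
  expect_true(all(file.exists(unlist(paths))))
  truth <- readr::read_csv(paths$truth, show_col_types = FALSE)
  w <- read_weather_csv(paths$weather)
  y <- read_yield_csv(paths$yields)
  cli <- seasonal_climate(impute_weather(w)$weather)
  res <- regress_cultivars(y, cli)
  for (v in c("T", "DTR", "R", "S")) {
    expect_equal(res[[paste0("beta_", v)]],
                 truth$value[truth$term == paste0("beta_", v)],
                 tolerance = 1e-8)
  }
})

test_that("toy-gap fixture loses two difference pairs to its gap year", {
  dir <- withr::local_tempdir()
  paths <- make_fixture("toy-gap", dir)
  y <- read_yield_csv(paths$yields)
  n_present <- nrow(y)  # 9 of the 10 span years; the gap removes two pairs
  expect_equal(n_present, 9L)
  fd <- first_difference(tibble::tibble(year = y$year, value = y$yield))
  expect_equal(nrow(fd), n_present - 2L)
})

test_that("toy-missingdays fixture yields exactly three imputed days", {
  dir <- withr::local_tempdir()
  paths <- make_fixture("toy-missingdays", dir)
  w <- read_weather_csv(paths$weather)
  qc <- impute_weather(w)
  miss_log <- qc$report$log[grepl("^missing", qc$report$log$rule), ]
  expect_equal(length(unique(miss_log$date)), 3L)
  expect_equal(qc$report$n_missing_days, 3L)
})
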