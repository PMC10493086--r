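test_that("elementary change arithmetic holds", {
  expect_equal(total_relative_change(0, 123), 0)
  expect_equal(total_relative_change(1, 1.5), 1.5)
  expect_equal(annual_actual_change(100, 1, 20), 5)
  expect_equal(annual_actual_change(100, 0, 20), 0)
  expect_error(annual_actual_change(100, 1, 0), class = "ricedelta_argument")
})

test_that("period deltas refit the trend inside the period", {
  # deterministic linear warming: 0.02 degC/yr in tavg
  # flat seasonal cycle so leap-day window shifts cannot perturb the slope
  sc <- weather_scenario(start_year = 1925, end_year = 1969,
                         trend_tmin = 0.02, trend_tmax = 0.02,
                         seasonal_amplitude = 0,
                         anomaly_sd = 0, rain_prob = 0, missing_rate = 0)
  cli <- seasonal_climate(synth_weather(sc))
  pd <- period_delta(cli, "T", "cool", c(1925, 1944))
  expect_equal(pd$delta_total, 0.02 * 19, tolerance = 1e-3)
  expect_equal(pd$n_years, 20L)
  # constant climate in the period gives a zero delta
  flat <- cli
  flat$T <- 20
  expect_equal(period_delta(flat, "T", "cool", c(1925, 1944))$delta_total, 0)
  # period-local slope equals the closed-form OLS oracle on those years
  cli2 <- make_climate(1990, 2009, seed = 31)
  sub <- cli2[cli2$season == "warm" & cli2$year >= 1995 & cli2$year <= 2004, ]
  oracle <- ols_oracle(sub$year, sub$R)
  pd2 <- period_delta(cli2, "R", "warm", c(1995, 2004))
  expect_equal(pd2$delta_total, unname(oracle["slope"]) * 9,
               tolerance = 1e-10)
  expect_error(period_delta(cli2, "T", "warm", c(2015, 2018)),
               class = "ricedelta_insufficient_data")
  expect_error(period_delta(cli2, "T", "warm", c(2004, 1995)),
               class = "ricedelta_argument")
})

make_projection_setup <- function() {
  cli <- make_climate(2000, 2019, seed = 37)
  cults <- dplyr::bind_rows(
    known_cultivar(2000, 2019),
    dplyr::mutate(known_cultivar(2000, 2019), id = "CV2",
                  beta_T = -20, intercept = 4000),
    dplyr::mutate(known_cultivar(2000, 2019), id = "CV3",
                  beta_DTR = 15, intercept = 6000)
  )
  yields <- synth_yields(yield_scenario(cults, seed = 5), cli)
  groups <- tibble::tibble(
    season = "cool", group = "2000-2019", start_year = 2000, end_year = 2019,
    cultivar = c("CV1", "CV2", "CV3"), excluded = FALSE
  )
  list(climate = cli, results = regress_cultivars(yields, cli),
       groups = groups)
}

test_that("relative and actual changes obey their consistency identity", {
  setup <- make_projection_setup()
  detail <- project_yield_changes(setup$results, setup$climate,
                                  groups = setup$groups, level = "cultivar")
  # annual_actual = (total_relative/100) * avg_yield / n_years row by row
  implied <- detail$total_relative / 100 * detail$avg_yield / detail$n_years
  expect_equal(detail$annual_actual, implied, tolerance = 1e-9)
  # sign coherence with the coefficient and the climate delta
  pct <- setup$results |>
    tidyr::pivot_longer(dplyr::starts_with("pct_"), names_to = "variable",
                        values_to = "pct", names_prefix = "pct_") |>
    dplyr::select(cultivar, variable, pct)
  joined <- dplyr::inner_join(detail, pct, by = c("cultivar", "variable"))
  expect_equal(sign(joined$total_relative),
               sign(joined$pct) * sign(joined$delta_total))
})

test_that("group projections average the member cultivars", {
  setup <- make_projection_setup()
  detail <- project_yield_changes(setup$results, setup$climate,
                                  groups = setup$groups, level = "cultivar")
  grp <- project_yield_changes(setup$results, setup$climate,
                               groups = setup$groups)
  for (v in c("T", "DTR", "R", "S")) {
    d <- detail[detail$variable == v, ]
    g <- grp[grp$variable == v, ]
    expect_equal(g$mean_total_relative, mean(d$total_relative))
    expect_equal(g$sd_total_relative, sd(d$total_relative))
    expect_equal(g$mean_annual_actual, mean(d$annual_actual))
    expect_equal(g$n_members, 3L)
  }
})

test_that("toy group of hand-set coefficients reproduces hand-computed products", {
  results <- tibble::tibble(
    season = "cool", cultivar = c("A", "B", "C"), avg_yield = 5000,
    beta_T = c(50, -25, 100), beta_DTR = 0, beta_R = 0, beta_S = 0,
    pct_T = c(1, -0.5, 2), pct_DTR = 0, pct_R = 0, pct_S = 0
  )
  # constant-slope climate so the delta is exact: T rises 0.05/yr
  years <- 2000:2019
  cli <- tibble::tibble(
    season = "cool", year = years, T = 20 + 0.05 * (years - 2000),
    DTR = 8, R = 500, S = 900
  )
  groups <- tibble::tibble(
    season = "cool", group = "g", start_year = 2000, end_year = 2019,
    cultivar = c("A", "B", "C"), excluded = FALSE
  )
  grp <- project_yield_changes(results, cli, groups = groups)
  t_row <- grp[grp$variable == "T", ]
  delta <- 0.05 * 19
  expect_equal(t_row$delta_total, delta, tolerance = 1e-9)
  expect_equal(t_row$mean_total_relative, mean(c(1, -0.5, 2) * delta),
               tolerance = 1e-9)
  expect_equal(t_row$mean_annual_actual, mean(c(50, -25, 100) * delta / 20),
               tolerance = 1e-9)
  # group mean of actual changes equals the change of the mean beta
  expect_equal(t_row$mean_annual_actual,
               mean(c(50, -25, 100)) * delta / 20, tolerance = 1e-9)
})

test_that("excluded groups are carried through with their flag", {
  setup <- make_projection_setup()
  groups <- dplyr::mutate(setup$groups, excluded = TRUE)
  grp <- project_yield_changes(setup$results, setup$climate, groups = groups)
  expect_true(all(grp$excluded))
})

test_that("global and period-local delta modes are both available and differ", {
  setup <- make_projection_setup()
  groups <- dplyr::mutate(setup$groups, start_year = 2005, end_year = 2014,
                          group = "2005-2014")
  per <- project_yield_changes(setup$results, setup$climate, groups = groups,
                               mode = "period")
  glo <- project_yield_changes(setup$results, setup$climate, groups = groups,
                               mode = "global")
  expect_equal(unique(per$mode), "period")
  expect_equal(unique(glo$mode), "global")
  expect_false(isTRUE(all.equal(per$delta_total, glo$delta_total)))
})
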