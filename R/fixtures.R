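#' Write a small deterministic test fixture
#'
#' Generates hand-checkable weather and yield CSVs (plus a pipeline config
#' and, where meaningful, a stored truth table) into `dir`. Fixtures are
#' tiny (at most ten years, one cultivar) and fully deterministic, so
#' downstream stages can be verified against stored expectations.
#'
#' Registered fixtures:
#' \describe{
#'   \item{`toy-linear`}{Ten years, one cultivar, noise-free yields linear
#'     in climate with a technology trend; `truth.csv` stores the exact
#'     generating coefficients that the regression must recover.}
#'   \item{`toy-gap`}{As `toy-linear` but with one missing experiment year,
#'     so the first-difference pair count drops by two.}
#'   \item{`toy-missingdays`}{Four years of weather with exactly three
#'     whole days blanked out, exercising the imputation path.}
#' }
#'
#' @param name Fixture name (see above).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture <- function(name, dir = tempfile("fixture")) {
  builders <- list(
    "toy-linear" = build_toy_linear,
    "toy-gap" = build_toy_gap,
    "toy-missingdays" = build_toy_missingdays
  )
  if (!name %in% names(builders)) {
    stop_ricedelta(
      sprintf("Unknown fixture '%s'; registered fixtures: %s.",
              name, paste(names(builders), collapse = ", ")),
      "lookup"
    )
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  invisible(builders[[name]](dir))
}

toy_weather_scenario <- function(start_year, end_year) {
  # Variable but noise-free-in-yield climate: temperature anomalies give the
  # first-difference design full rank.
  weather_scenario(
    start_year = start_year, end_year = end_year,
    ar1_coeff = 0.3, anomaly_sd = 1.2,
    rain_prob = 0.3, missing_rate = 0, seed = 42L
  )
}

toy_truth <- tibble::tibble(
  term = c("beta0", "beta_T", "beta_DTR", "beta_R", "beta_S", "tech_trend"),
  value = c(5000, 50, -30, 0.5, 1.2, 25)
)

toy_config <- function(dir, gap_years = integer()) {
  list(
    weather = file.path(dir, "weather.csv"),
    yields = file.path(dir, "yields.csv"),
    outlier_z = 4,
    impute_fallback = "climatology",
    delta_mode = "period",
    min_pairs = 6,
    seasons = purrr::pmap(default_seasons(), function(name, start, end) {
      list(name = name, start = start, end = end)
    }),
    cultivars = list(list(id = "CV1", season = "cool",
                          spans = list(c(2000, 2009)))),
    groups = list(list(id = "2000-2009", season = "cool",
                       start = 2000, end = 2009,
                       members = list("CV1"), excluded = FALSE)),
    gap_years = as.list(gap_years)
  )
}

toy_cultivar <- function() {
  tibble(
    id = "CV1", season = "cool", first_year = 2000, last_year = 2009,
    intercept = toy_truth$value[toy_truth$term == "beta0"],
    tech_trend = toy_truth$value[toy_truth$term == "tech_trend"],
    beta_T = toy_truth$value[toy_truth$term == "beta_T"],
    beta_DTR = toy_truth$value[toy_truth$term == "beta_DTR"],
    beta_R = toy_truth$value[toy_truth$term == "beta_R"],
    beta_S = toy_truth$value[toy_truth$term == "beta_S"],
    noise_sd = 0
  )
}

write_toy <- function(dir, weather, yields, config, truth = NULL) {
  paths <- list(
    weather = file.path(dir, "weather.csv"),
    yields = file.path(dir, "yields.csv"),
    config = file.path(dir, "config.yml")
  )
  write_weather_csv(weather, paths$weather)
  write_yield_csv(yields, paths$yields)
  yaml::write_yaml(config, paths$config)
  if (!is.null(truth)) {
    paths$truth <- file.path(dir, "truth.csv")
    readr::write_csv(truth, paths$truth)
  }
  paths
}

build_toy_linear <- function(dir) {
  weather <- synth_weather(toy_weather_scenario(2000, 2009))
  # yields are generated from the QC'd climate, the same view the pipeline
  # regresses against, so the stored truth is exact end to end
  climate <- seasonal_climate(impute_weather(weather)$weather)
  yields <- synth_yields(yield_scenario(toy_cultivar(), seed = 7L), climate)
  write_toy(dir, weather, yields, toy_config(dir), truth = toy_truth)
}

build_toy_gap <- function(dir) {
  weather <- synth_weather(toy_weather_scenario(2000, 2009))
  climate <- seasonal_climate(impute_weather(weather)$weather)
  yields <- synth_yields(
    yield_scenario(toy_cultivar(), gap_years = 2004L, seed = 7L), climate
  )
  write_toy(dir, weather, yields, toy_config(dir, gap_years = 2004L),
            truth = toy_truth)
}

build_toy_missingdays <- function(dir) {
  weather <- synth_weather(toy_weather_scenario(2000, 2003))
  missing_days <- as.Date(c("2001-03-10", "2001-08-15", "2002-05-02"))
  weather[weather$date %in% missing_days,
          c("tavg", "tmin", "tmax", "rain", "sunshine")] <- NA_real_
  climate <- seasonal_climate(impute_weather(weather)$weather)
  cult <- toy_cultivar()
  cult$first_year <- 2000
  cult$last_year <- 2003
  yields <- synth_yields(yield_scenario(cult, seed = 7L), climate)
  cfg <- toy_config(dir)
  cfg$cultivars[[1]]$spans <- list(c(2000, 2003))
  cfg$groups[[1]]$id <- "2000-2003"
  cfg$groups[[1]]$start <- 2000
  cfg$groups[[1]]$end <- 2003
  write_toy(dir, weather, yields, cfg)
}
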