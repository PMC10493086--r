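#' Read and write the pipeline's CSV dialects
#'
#' Daily weather files carry the header
#' `date,tavg,tmin,tmax,rain,sunshine` (ISO-8601 dates, empty field =
#' missing); yield files carry `cultivar,season,year,yield`.
#'
#' @param path File path.
#' @param weather,yields Tibbles to write.
#' @return The tibble read, or (for writers) the input invisibly.
#' @name weather_io
NULL

#' @rdname weather_io
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) {
    stop_ricedelta(sprintf("Weather file '%s' does not exist.", path),
                   "config")
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      tavg = readr::col_double(), tmin = readr::col_double(),
      tmax = readr::col_double(), rain = readr::col_double(),
      sunshine = readr::col_double()
    )
  )
  check_columns(out, c("date", weather_value_cols), sprintf("'%s'", path))
  out
}

#' @rdname weather_io
#' @export
write_weather_csv <- function(weather, path) {
  check_columns(weather, c("date", weather_value_cols), "`weather`")
  readr::write_csv(weather, path, na = "")
  invisible(weather)
}

#' @rdname weather_io
#' @export
read_yield_csv <- function(path) {
  if (!file.exists(path)) {
    stop_ricedelta(sprintf("Yield file '%s' does not exist.", path), "config")
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      cultivar = readr::col_character(), season = readr::col_character(),
      year = readr::col_integer(), yield = readr::col_double()
    )
  )
  check_columns(out, c("cultivar", "season", "year", "yield"),
                sprintf("'%s'", path))
  out
}

#' @rdname weather_io
#' @export
write_yield_csv <- function(yields, path) {
  check_columns(yields, c("cultivar", "season", "year", "yield"), "`yields`")
  readr::write_csv(yields, path, na = "")
  invisible(yields)
}

#' Read an analysis configuration
#'
#' The configuration is a YAML file declaring input paths (`weather`,
#' `yields`), season windows, cultivar cultivation spans, group membership,
#' optional analysis `periods`, and the knobs `outlier_z`,
#' `impute_fallback`, `delta_mode` (`"period"` or `"global"`) and
#' `min_pairs`. See [make_fixture()] for a complete example file.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    stop_ricedelta(sprintf("Config file '%s' does not exist.", path), "config")
  }
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  as_analysis_config(
    modifyList(raw, list(weather = resolve(raw$weather),
                         yields = resolve(raw$yields)))
  )
}

as_analysis_config <- function(x) {
  for (field in c("weather", "yields")) {
    if (is.null(x[[field]])) {
      stop_ricedelta(sprintf("Config is missing the '%s' path.", field),
                     "config")
    }
  }
  x$outlier_z <- x$outlier_z %||% 4
  x$impute_fallback <- x$impute_fallback %||% "climatology"
  x$delta_mode <- x$delta_mode %||% "period"
  x$min_pairs <- x$min_pairs %||% 6
  if (!x$delta_mode %in% c("period", "global")) {
    stop_ricedelta("`delta_mode` must be 'period' or 'global'.", "config")
  }
  x$seasons <- if (is.null(x$seasons)) default_seasons() else {
    bind_rows(lapply(x$seasons, function(s) {
      tibble(name = s$name, start = s$start, end = s$end)
    }))
  }
  x$spans <- if (is.null(x$cultivars)) taichung_cultivars() else {
    bind_rows(lapply(x$cultivars, function(cv) {
      bind_rows(lapply(cv$spans, function(sp) {
        tibble(cultivar = cv$id, season = cv$season,
               first_year = as.integer(sp[[1]]),
               last_year = as.integer(sp[[2]]))
      }))
    }))
  }
  x$group_table <- if (is.null(x$groups)) taichung_groups() else {
    bind_rows(lapply(x$groups, function(g) {
      tibble(season = g$season, group = g$id,
             start_year = as.integer(g$start), end_year = as.integer(g$end),
             cultivar = unlist(g$members),
             excluded = isTRUE(g$excluded))
    }))
  }
  if (!is.null(x$periods)) {
    x$periods <- lapply(x$periods, function(p) as.integer(unlist(p)))
  }
  structure(x, class = "analysis_config")
}

# Empty-but-typed output schemas, so tiny runs still write valid tables.
empty_results <- function() {
  tibble(season = character(), cultivar = character(), n_pairs = integer(),
         avg_yield = numeric(), beta0 = numeric(), beta_T = numeric(),
         beta_DTR = numeric(), beta_R = numeric(), beta_S = numeric(),
         pct_T = numeric(), pct_DTR = numeric(), pct_R = numeric(),
         pct_S = numeric(), r2 = numeric())
}

empty_projection <- function() {
  tibble(season = character(), group = character(), start_year = integer(),
         end_year = integer(), variable = character(),
         delta_total = numeric(), mean_total_relative = numeric(),
         sd_total_relative = numeric(), mean_annual_actual = numeric(),
         sd_annual_actual = numeric(), n_years = integer(),
         n_members = integer(), excluded = logical(), mode = character())
}

empty_group_summary <- function() {
  tibble(season = character(), group = character(), start_year = integer(),
         end_year = integer(), variable = character(), mean_pct = numeric(),
         sd_pct = numeric(), n_members = integer(), excluded = logical())
}

#' Run the yield-climate analysis pipeline end to end
#'
#' Executes every stage from a single configuration: weather QC and
#' seasonal aggregation, climate trend fits, per-cultivar first-difference
#' regressions, group summaries and correlation tables, and yield-change
#' projections. All tables are written to `out_dir` at full precision
#' (rounding is a rendering concern; see [render_report()]), together with
#' a line-oriented QC log and a run manifest recording the configuration
#' hash and package version. Reruns on identical inputs are bit-identical.
#' If any stage fails, the partial outputs of this run are removed.
#'
#' @param config An `analysis_config`, or the path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, the manifest list (`outputs` has the written paths).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) {
    config <- read_analysis_config(config)
  }
  if (!inherits(config, "analysis_config")) {
    config <- as_analysis_config(config)
  }
  for (field in c("weather", "yields")) {
    if (!file.exists(config[[field]])) {
      stop_ricedelta(
        sprintf("Config '%s' path '%s' does not exist.", field,
                config[[field]]),
        "config"
      )
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tbl, path, na = "")
    written <<- c(written, path)
    path
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop_ricedelta(
        sprintf("Pipeline stage '%s' failed: %s", label, conditionMessage(e)),
        "pipeline", parent = e
      )
    })
  }

  say("stage weather_qc")
  qc <- stage("weather_qc", {
    weather <- read_weather_csv(config$weather)
    impute_weather(weather, outlier_z = config$outlier_z,
                   fallback = config$impute_fallback)
  })
  climate <- stage("aggregate", {
    seasonal_climate(qc$weather, seasons = config$seasons,
                     report = qc$report)
  })
  emit(climate, "seasonal_climate.csv")
  log_path <- file.path(out_dir, "qc_log.txt")
  stage("qc_log", {
    lines <- c(
      sprintf("missing cells: %d/%d (%.4f%%)", qc$report$n_missing_cells,
              qc$report$n_cells, 100 * qc$report$fraction_missing_cells),
      sprintf("missing whole days: %d/%d (%.4f%%)", qc$report$n_missing_days,
              qc$report$n_days, 100 * qc$report$fraction_missing_days),
      sprintf("replaced: %d missing, %d outliers; unresolved: %d",
              qc$report$n_missing_replaced, qc$report$n_outliers_replaced,
              qc$report$n_unresolved),
      sprintf("%s %s old=%s new=%s rule=%s", qc$report$log$date,
              qc$report$log$variable, format(qc$report$log$old),
              format(qc$report$log$new), qc$report$log$rule)
    )
    writeLines(lines, log_path)
    written <<- c(written, log_path)
  })

  say("stage trends")
  periods <- config$periods %||% unname(
    purrr::pmap(
      dplyr::distinct(config$group_table, .data$start_year, .data$end_year),
      function(start_year, end_year) c(start_year, end_year)
    )
  )
  trends <- stage("trends", climate_trends(climate, periods = periods))
  emit(trends, "climate_trends.csv")

  say("stage delta_regression")
  results <- stage("delta_regression", {
    yields <- read_yield_csv(config$yields)
    grouped_ids <- unique(config$group_table$cultivar)
    absent <- setdiff(grouped_ids, unique(yields$cultivar))
    if (length(absent) > 0L) {
      stop_ricedelta(
        sprintf("Grouped cultivar%s %s missing from the yield table.",
                if (length(absent) > 1L) "s" else "",
                paste(absent, collapse = ", ")),
        "config"
      )
    }
    res <- regress_cultivars(yields, climate, min_pairs = config$min_pairs)
    list(yields = yields, results = if (nrow(res) == 0L) empty_results() else res)
  })
  emit(results$results, "regression_results.csv")

  say("stage grouping")
  groups <- stage("grouping", {
    build_groups(config$spans, mode = "config", groups = config$group_table)
  })
  summaries <- stage("grouping", {
    s <- group_summaries(results$results, groups = groups)
    if (nrow(s) == 0L) empty_group_summary() else s
  })
  emit(summaries, "group_summary.csv")
  correlations <- stage("grouping", {
    bind_rows(lapply(unique(climate$season), function(s) {
      tidy(climate_delta_correlations(climate, s))
    }))
  })
  emit(correlations, "correlations.csv")
  yield_cors <- stage("grouping", {
    yc <- pairwise_yield_correlations(results$yields, groups = groups)
    if (nrow(yc) == 0L) {
      tibble(season = character(), group = character(),
             cultivar_a = character(), cultivar_b = character(),
             r = numeric(), n = integer(), marker = character())
    } else yc
  })
  emit(yield_cors, "yield_correlations.csv")

  say("stage projection")
  changes <- stage("projection", {
    if (nrow(results$results) == 0L) empty_projection() else {
      project_yield_changes(results$results, climate, groups = groups,
                            mode = config$delta_mode)
    }
  })
  emit(changes, "yield_changes.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ricedelta")),
    config_hash = rlang::hash(unclass(config)),
    delta_mode = config$delta_mode,
    outputs = as.list(basename(written))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  say("done")
  invisible(manifest)
}

#' Generate pipeline-ready synthetic input files
#'
#' Wraps [synth_weather()] and [synth_yields()]: generates a daily weather
#' CSV and a cultivar yield CSV (plus the seasonal climate used to build
#' the yields) under `out_dir`.
#'
#' @param weather_sc A [weather_scenario()] (or path to a YAML file of its
#'   arguments).
#' @param yield_sc A [yield_scenario()] (or path to a YAML file with
#'   `cultivars`, `gap_years`, `seed`).
#' @param out_dir Output directory.
#' @param seed Optional integer overriding both scenario seeds (the yield
#'   scenario uses `seed + 1`).
#' @return Invisibly, a list with paths `weather` and `yields`.
#' @export
simulate_inputs <- function(weather_sc = weather_scenario(),
                            yield_sc = default_yield_scenario(),
                            out_dir = tempfile("simulated"), seed = NULL) {
  if (is.character(weather_sc)) {
    weather_sc <- do.call(weather_scenario, yaml::read_yaml(weather_sc))
  }
  if (is.character(yield_sc)) {
    raw <- yaml::read_yaml(yield_sc)
    yield_sc <- yield_scenario(
      bind_rows(lapply(raw$cultivars, as_tibble)),
      gap_years = as.integer(unlist(raw$gap_years)),
      seed = raw$seed %||% 1L
    )
  }
  if (!is.null(seed)) {
    weather_sc$seed <- as.integer(seed)
    yield_sc$seed <- as.integer(seed) + 1L
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  weather <- synth_weather(weather_sc)
  clean <- impute_weather(weather, fallback = "climatology")
  climate <- seasonal_climate(clean$weather)
  yields <- synth_yields(yield_sc, climate)
  paths <- list(weather = file.path(out_dir, "weather.csv"),
                yields = file.path(out_dir, "yields.csv"))
  write_weather_csv(weather, paths$weather)
  write_yield_csv(yields, paths$yields)
  invisible(paths)
}

#' Default synthetic yield scenario emulating the Taichung trial layout
#'
#' One contiguous-span cultivar entry per trial cultivar (using the overall
#' first and last trial year of each), the trial-wide gap years, and
#' season-dependent climate sensitivities of realistic magnitude: warm
#' season yields respond negatively to temperature, cool season positively;
#' both respond negatively to DTR; rainfall and sunshine effects are weak.
#'
#' @param noise_sd Yield noise SD in kg/ha.
#' @param seed Integer seed.
#' @return A [yield_scenario()].
#' @export
default_yield_scenario <- function(noise_sd = 400, seed = 2L) {
  spans <- taichung_cultivars() |>
    group_by(.data$cultivar, .data$season) |>
    summarise(first_year = min(.data$first_year),
              last_year = max(.data$last_year), .groups = "drop")
  cultivars <- spans |>
    mutate(
      id = .data$cultivar,
      intercept = ifelse(.data$season == "cool", 4800, 4200),
      tech_trend = 25,
      beta_T = ifelse(.data$season == "cool", 60, -45),
      beta_DTR = ifelse(.data$season == "cool", -35, -12),
      beta_R = -0.3,
      beta_S = 0.8,
      noise_sd = noise_sd
    ) |>
    select("id", "season", "first_year", "last_year", "intercept",
           "tech_trend", "beta_T", "beta_DTR", "beta_R", "beta_S", "noise_sd")
  yield_scenario(cultivars, gap_years = taichung_gap_years(), seed = seed)
}

#' Render rounded report tables from a pipeline output directory
#'
#' Reads the full-precision CSV outputs of [run_pipeline()] and returns
#' them with numeric columns rounded to two decimals, the precision used in
#' published summary tables.
#'
#' @param dir A [run_pipeline()] output directory.
#' @param digits Decimal places; default 2.
#' @return A named list of tibbles.
#' @export
render_report <- function(dir, digits = 2) {
  files <- c("seasonal_climate", "climate_trends", "regression_results",
             "group_summary", "correlations", "yield_changes")
  out <- lapply(files, function(f) {
    path <- file.path(dir, paste0(f, ".csv"))
    if (!file.exists(path)) {
      stop_ricedelta(sprintf("'%s' not found in '%s'.", basename(path), dir),
                     "config")
    }
    tbl <- readr::read_csv(path, show_col_types = FALSE)
    mutate(tbl, across(dplyr::where(is.double), ~ round(.x, digits)))
  })
  setNames(out, files)
}
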