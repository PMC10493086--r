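#' Default cropping-season windows
#'
#' The cool cropping season runs January 20 to June 23 and the warm cropping
#' season July 4 to November 22, the calendar windows over which seasonal
#' climate is aggregated. Windows are date-anchored, so leap years add one
#' day to the cool window.
#'
#' @return A tibble with columns `name`, `start`, `end` (month-day strings).
#' @export
default_seasons <- function() {
  tibble(
    name = c("cool", "warm"),
    start = c("01-20", "07-04"),
    end = c("06-23", "11-22")
  )
}

weather_value_cols <- c("tavg", "tmin", "tmax", "rain", "sunshine")

# Day-of-year climatology (mean and SD per variable) over a +/- `half_window`
# day window, pooled across all years. Used for outlier screening and as the
# optional last-resort fill.
doy_climatology <- function(doy, values_by_var, half_window = 7) {
  max_doy <- 366L
  idx_by_doy <- lapply(seq_len(max_doy), function(d) {
    dist <- abs(doy - d)
    which(pmin(dist, max_doy - dist) <= half_window)
  })
  lapply(values_by_var, function(v) {
    m <- vapply(idx_by_doy, function(i) mean(v[i], na.rm = TRUE), numeric(1))
    s <- vapply(idx_by_doy, function(i) sd(v[i], na.rm = TRUE), numeric(1))
    list(mean = m, sd = s)
  })
}

#' Impute missing values and outliers in a daily weather series
#'
#' A missing or outlying value on calendar day (month, day) of year `y` is
#' replaced by the mean of the same calendar day's values in years `y - 1`
#' and `y + 1`; if only one neighbouring year has a usable value, that value
#' is used alone. Outliers are values further than `outlier_z` climatological
#' standard deviations from the day-of-year climatological mean (computed
#' over a +/- 7 day window pooled across all years). When both neighbouring
#' years are unusable the cell is left absent and flagged unresolved, unless
#' `fallback = "climatology"`, in which case the day-of-year climatological
#' mean fills it (each such fill is logged with rule `"climatology"`).
#'
#' Every replacement is enumerated in the returned QC report, which also
#' exposes the missing fraction both as day-variable cells and as whole
#' missing days.
#'
#' @param weather Daily weather tibble with columns `date`, `tavg`, `tmin`,
#'   `tmax`, `rain`, `sunshine` (`NA` = absent).
#' @param outlier_z Robustness threshold in climatological standard
#'   deviations; default 4, deliberately conservative so genuine extremes
#'   (typhoon rainfall) survive.
#' @param fallback `"none"` (default) leaves doubly-missing cells absent;
#'   `"climatology"` fills them from the day-of-year climatology.
#' @return A list with elements `weather` (the cleaned tibble) and `report`
#'   (a `qc_report`; see Details).
#' @details The `qc_report` contains counts (`n_missing_replaced`,
#'   `n_outliers_replaced`, `n_unresolved`, `n_missing_cells`,
#'   `n_missing_days`, `fraction_missing_cells`, `fraction_missing_days`)
#'   and a `log` tibble with one row per replacement (`date`, `variable`,
#'   `old`, `new`, `rule`).
#' @export
impute_weather <- function(weather, outlier_z = 4,
                           fallback = c("none", "climatology")) {
  fallback <- match.arg(fallback)
  check_number(outlier_z, "outlier_z", min = 0, allow_min = FALSE)
  weather <- as_tibble(weather)
  check_columns(weather, c("date", weather_value_cols), "`weather`")
  weather <- arrange(weather, .data$date)
  n <- nrow(weather)
  md <- month_day(weather$date)
  year <- as.integer(format(weather$date, "%Y"))
  doy <- as.POSIXlt(weather$date)$yday + 1

  n_years <- length(unique(year))
  values <- lapply(weather[weather_value_cols], as.numeric)
  clim <- doy_climatology(doy, values)

  # Row lookup by (year, month-day); -1 marks absent calendar days.
  key <- paste(year, md)
  row_of <- setNames(seq_len(n), key)
  neighbour_row <- function(y, m) {
    r <- row_of[paste(y, m)]
    if (is.na(r)) -1L else unname(r)
  }

  log_rows <- list()
  out <- weather
  n_missing_cells <- 0L
  n_missing_replaced <- 0L
  n_outliers_replaced <- 0L
  n_unresolved <- 0L

  for (var in weather_value_cols) {
    v <- values[[var]]
    cm <- clim[[var]]$mean[doy]
    cs <- clim[[var]]$sd[doy]
    is_missing <- is.na(v)
    is_outlier <- !is_missing & !is.na(cs) & cs > 0 &
      abs(v - cm) > outlier_z * cs
    n_missing_cells <- n_missing_cells + sum(is_missing)
    bad <- which(is_missing | is_outlier)
    if (length(bad) == 0L) next
    usable <- !is_missing & !is_outlier   # donor cells: original good values
    new_v <- v
    for (i in bad) {
      donors <- c(neighbour_row(year[i] - 1L, md[i]),
                  neighbour_row(year[i] + 1L, md[i]))
      donors <- donors[donors > 0L]
      donors <- donors[usable[donors]]
      if (length(donors) >= 1L) {
        repl <- mean(v[donors])
        rule <- if (is_outlier[i]) {
          if (length(donors) == 2L) "outlier_neighbour_mean"
          else "outlier_single_neighbour"
        } else {
          if (length(donors) == 2L) "missing_neighbour_mean"
          else "missing_single_neighbour"
        }
        new_v[i] <- repl
        if (is_outlier[i]) n_outliers_replaced <- n_outliers_replaced + 1L
        else n_missing_replaced <- n_missing_replaced + 1L
      } else if (fallback == "climatology" && !is.na(cm[i])) {
        repl <- cm[i]
        rule <- "climatology"
        new_v[i] <- repl
        if (is_outlier[i]) n_outliers_replaced <- n_outliers_replaced + 1L
        else n_missing_replaced <- n_missing_replaced + 1L
      } else if (is_outlier[i]) {
        # no usable donor: keep the suspect value rather than destroy data
        repl <- v[i]
        rule <- "outlier_unresolved_kept"
        n_unresolved <- n_unresolved + 1L
      } else {
        repl <- NA_real_
        rule <- "unresolved"
        new_v[i] <- NA_real_
        n_unresolved <- n_unresolved + 1L
      }
      log_rows[[length(log_rows) + 1L]] <- tibble(
        date = weather$date[i], variable = var,
        old = v[i], new = repl, rule = rule
      )
    }
    out[[var]] <- new_v
  }

  log <- if (length(log_rows) > 0L) bind_rows(log_rows) else {
    tibble(date = as.Date(character()), variable = character(),
           old = numeric(), new = numeric(), rule = character())
  }
  all_missing_day <- rowSums(is.na(weather[weather_value_cols])) ==
    length(weather_value_cols)
  report <- structure(
    list(
      n_missing_replaced = n_missing_replaced,
      n_outliers_replaced = n_outliers_replaced,
      n_unresolved = n_unresolved,
      n_missing_cells = n_missing_cells,
      n_missing_days = sum(all_missing_day),
      n_cells = n * length(weather_value_cols),
      n_days = n,
      fraction_missing_cells = n_missing_cells / (n * length(weather_value_cols)),
      fraction_missing_days = sum(all_missing_day) / n,
      short_series = n_years < 3L,
      outlier_z = outlier_z,
      fallback = fallback,
      log = log
    ),
    class = "qc_report"
  )
  list(weather = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  days: %d  (missing whole days: %d, %.2f%%)\n",
              x$n_days, x$n_missing_days, 100 * x$fraction_missing_days))
  cat(sprintf("  day-variable cells: %d  (missing: %d, %.2f%%)\n",
              x$n_cells, x$n_missing_cells, 100 * x$fraction_missing_cells))
  cat(sprintf("  replaced: %d missing, %d outliers (z > %g); unresolved: %d\n",
              x$n_missing_replaced, x$n_outliers_replaced, x$outlier_z,
              x$n_unresolved))
  if (x$short_series) {
    cat("  note: series shorter than 3 years; neighbour-year imputation limited\n")
  }
  invisible(x)
}

#' Aggregate daily weather into one seasonal climate record
#'
#' Over the season's calendar window (inclusive of both endpoints) computes
#' the seasonal mean daily average temperature `T`, mean diurnal temperature
#' range `DTR = mean(tmax - tmin)`, total rainfall `R` and total sunshine
#' duration `S`.
#'
#' @param weather Cleaned daily weather tibble.
#' @param season One row of a season table (list or one-row data frame with
#'   `name`, `start`, `end`).
#' @param year Calendar year of the window.
#' @param report Optional `qc_report` from [impute_weather()]; if supplied,
#'   `n_imputed` counts the logged replacements falling inside the window.
#' @return A one-row tibble: `season`, `year`, `T`, `DTR`, `R`, `S`,
#'   `n_days`, `n_imputed`.
#' @export
aggregate_season <- function(weather, season, year, report = NULL) {
  season <- as.list(season)
  window <- season_window(season, year)
  rows <- weather[weather$date %in% window, ]
  if (nrow(rows) < length(window)) {
    missing_days <- setdiff(as.character(window), as.character(rows$date))
    stop_ricedelta(
      sprintf("Season '%s' %d: day %s absent from the weather series.",
              season$name, year, missing_days[1]),
      "aggregation"
    )
  }
  incomplete <- rowSums(is.na(rows[weather_value_cols])) > 0L
  if (any(incomplete)) {
    stop_ricedelta(
      sprintf(
        "Season '%s' %d: unresolved missing values on %s%s.",
        season$name, year, as.character(rows$date[incomplete][1]),
        if (sum(incomplete) > 1L)
          sprintf(" (and %d more days)", sum(incomplete) - 1L) else ""
      ),
      "aggregation"
    )
  }
  n_imputed <- if (is.null(report)) 0L else {
    replaced <- !report$log$rule %in% c("unresolved", "outlier_unresolved_kept")
    sum(report$log$date %in% window & replaced)
  }
  tibble(
    season = season$name, year = as.integer(year),
    T = mean(rows$tavg), DTR = mean(rows$tmax - rows$tmin),
    R = sum(rows$rain), S = sum(rows$sunshine),
    n_days = length(window), n_imputed = as.integer(n_imputed)
  )
}

#' Aggregate daily weather into a seasonal climate table
#'
#' Applies [aggregate_season()] over every season and every year whose
#' window is fully covered by the supplied series.
#'
#' @param weather Cleaned daily weather tibble.
#' @param seasons Season table as from [default_seasons()].
#' @param years Years to aggregate; by default all years whose windows lie
#'   inside the series' date range.
#' @param report Optional `qc_report`, passed through to
#'   [aggregate_season()].
#' @return A tibble with one row per season-year.
#' @export
seasonal_climate <- function(weather, seasons = default_seasons(),
                             years = NULL, report = NULL) {
  weather <- as_tibble(weather)
  check_columns(weather, c("date", weather_value_cols), "`weather`")
  seasons <- as_tibble(seasons)
  check_columns(seasons, c("name", "start", "end"), "`seasons`")
  rng <- range(weather$date)
  rows <- purrr::pmap(seasons, function(name, start, end) {
    season <- list(name = name, start = start, end = end)
    yrs <- years
    if (is.null(yrs)) {
      all_years <- seq(as.integer(format(rng[1], "%Y")),
                       as.integer(format(rng[2], "%Y")))
      yrs <- all_years[vapply(all_years, function(y) {
        w <- season_window(season, y)
        w[1] >= rng[1] && w[length(w)] <= rng[2]
      }, logical(1))]
    }
    bind_rows(lapply(yrs, function(y) {
      aggregate_season(weather, season, y, report = report)
    }))
  })
  bind_rows(rows) |> arrange(.data$season, .data$year)
}
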