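# Internal error helper: all package errors carry a "ricedelta_<class>"
# condition class so callers (and tests) can branch on the failure kind.
stop_ricedelta <- function(msg, class, ...) {
  rlang::abort(msg, class = paste0("ricedelta_", class), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_min = TRUE, allow_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_ricedelta(sprintf("`%s` must be a single number.", name), "config")
  }
  lo_ok <- if (allow_min) x >= min else x > min
  hi_ok <- if (allow_max) x <= max else x < max
  if (!lo_ok || !hi_ok) {
    stop_ricedelta(
      sprintf(
        "`%s` = %g is outside its valid range %s%g, %g%s.", name, x,
        if (allow_min) "[" else "(", min, max, if (allow_max) "]" else ")"
      ),
      "config"
    )
  }
  invisible(x)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_ricedelta(
      sprintf(
        "%s is missing required column%s: %s.", what,
        if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
      ),
      "config"
    )
  }
  invisible(data)
}

# Month-day key ("03-05") used to match the same calendar day across years.
month_day <- function(dates) format(dates, "%m-%d")

# Inclusive calendar window of a season within one year.
season_window <- function(season, year) {
  start <- as.Date(sprintf("%d-%s", year, season$start))
  end <- as.Date(sprintf("%d-%s", year, season$end))
  if (is.na(start) || is.na(end) || start >= end) {
    stop_ricedelta(
      sprintf("Season '%s' has an invalid window %s..%s for year %d.",
              season$name, season$start, season$end, year),
      "config"
    )
  }
  seq(start, end, by = "day")
}
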