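#' First differences of an annual series
#'
#' For each year `y` with both `y` and `y + 1` present, the difference
#' `value(y + 1) - value(y)`, keyed by the earlier year. Gaps in the series
#' produce no bridging pair, so differencing never spans years in which no
#' experiment was run — the property that makes first differencing remove
#' slowly varying technology trends.
#'
#' @param series A data frame with columns `year` and `value`, or a numeric
#'   vector named by year.
#' @return A tibble with columns `year` (the earlier year of the pair) and
#'   `delta`. May be empty.
#' @export
#' @examples
#' first_difference(c("1" = 10, "2" = 12, "3" = 14))
first_difference <- function(series) {
  if (is.numeric(series) && !is.null(names(series))) {
    series <- tibble(year = as.integer(names(series)), value = unname(series))
  }
  series <- as_tibble(series)
  check_columns(series, c("year", "value"), "`series`")
  series <- series[!is.na(series$value), ]
  series <- arrange(series, .data$year)
  if (nrow(series) < 2L) {
    return(tibble(year = integer(), delta = numeric()))
  }
  has_next <- (series$year + 1L) %in% series$year
  y <- series$year[has_next]
  nxt <- match(y + 1L, series$year)
  tibble(year = as.integer(y), delta = series$value[nxt] - series$value[match(y, series$year)])
}

# First differences of the seasonal climate variables, one row per season
# and earlier year of a consecutive pair.
climate_first_differences <- function(climate) {
  climate <- as_tibble(climate)
  check_columns(climate, c("season", "year", climate_vars), "`climate`")
  purrr::map(unique(climate$season), function(s) {
    sub <- climate[climate$season == s, ]
    diffs <- lapply(climate_vars, function(v) {
      first_difference(tibble(year = sub$year, value = sub[[v]]))
    })
    out <- diffs[[1]]["year"]
    for (i in seq_along(climate_vars)) {
      out[[paste0("d", climate_vars[i])]] <-
        diffs[[i]]$delta[match(out$year, diffs[[i]]$year)]
    }
    mutate(out, season = s, .before = 1)
  }) |> bind_rows()
}

#' Build joined yield-climate first-difference sets
#'
#' For every cultivar-season, pairs consecutive trial years (no pair spans a
#' gap) and joins the matching climate first differences for that season,
#' shared across cultivars.
#'
#' @param yields Yield tibble (`cultivar`, `season`, `year`, `yield`).
#' @param climate Seasonal climate tibble (`season`, `year`, `T`, `DTR`,
#'   `R`, `S`).
#' @return A tibble with columns `cultivar`, `season`, `year` (earlier year
#'   of the pair), `dY`, `dT`, `dDTR`, `dR`, `dS`.
#' @export
build_first_differences <- function(yields, climate) {
  yields <- as_tibble(yields)
  check_columns(yields, c("cultivar", "season", "year", "yield"), "`yields`")
  cdiff <- climate_first_differences(climate)
  yields |>
    group_by(.data$cultivar, .data$season) |>
    dplyr::group_modify(function(df, key) {
      fd <- first_difference(tibble(year = df$year, value = df$yield))
      rename(fd, dY = "delta")
    }) |>
    ungroup() |>
    inner_join(cdiff, by = c("season", "year")) |>
    arrange(.data$season, .data$cultivar, .data$year)
}

#' Fit the first-difference yield-climate regression for one cultivar
#'
#' Ordinary least squares of yield first differences on the four climate
#' first differences,
#' `dY = b0 + b_T dT + b_DTR dDTR + b_R dR + b_S dS + e`,
#' with percent coefficients `pct_v = 100 * beta_v / avg_yield` expressing
#' the response as percent of the cultivar's average grain yield per unit of
#' climate change.
#'
#' @param diffs First-difference tibble with columns `dY`, `dT`, `dDTR`,
#'   `dR`, `dS` (one cultivar-season's pairs).
#' @param avg_yield The cultivar's average grain yield over its trial years
#'   (kg/ha, > 0), the denominator of the percent coefficients.
#' @param min_pairs Minimum number of difference pairs for a reported fit;
#'   default 6 keeps the five-parameter model determined with at least one
#'   residual degree of freedom.
#' @return A `delta_fit` object: coefficients `beta0`, `beta_T`, `beta_DTR`,
#'   `beta_R`, `beta_S`, their standard errors `se`, percent forms `pct_T`
#'   ... `pct_S`, `n_pairs`, `r2`, `avg_yield`.
#' @export
fit_delta_regression <- function(diffs, avg_yield, min_pairs = 6) {
  diffs <- as_tibble(diffs)
  pred_cols <- paste0("d", climate_vars)
  check_columns(diffs, c("dY", pred_cols), "`diffs`")
  check_number(avg_yield, "avg_yield")
  if (avg_yield <= 0) {
    stop_ricedelta("`avg_yield` must be positive.", "argument")
  }
  diffs <- diffs[stats::complete.cases(diffs[c("dY", pred_cols)]), ]
  if (nrow(diffs) < min_pairs) {
    stop_ricedelta(
      sprintf("Need at least %d first-difference pairs, got %d.",
              min_pairs, nrow(diffs)),
      "insufficient_data"
    )
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(diffs[pred_cols]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_ricedelta(
      sprintf("Collinear first-difference design; offending column%s: %s.",
              if (length(dropped) > 1L) "s" else "",
              paste(dropped, collapse = ", ")),
      "rank"
    )
  }
  fit <- lm(dY ~ dT + dDTR + dR + dS, data = diffs)
  sm <- suppressWarnings(summary(fit))  # exact fits warn about perfect R2
  beta <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  pct <- 100 * beta[pred_cols] / avg_yield
  structure(
    list(
      beta0 = unname(beta[["(Intercept)"]]),
      beta_T = unname(beta[["dT"]]), beta_DTR = unname(beta[["dDTR"]]),
      beta_R = unname(beta[["dR"]]), beta_S = unname(beta[["dS"]]),
      se = se,
      pct_T = unname(pct[["dT"]]), pct_DTR = unname(pct[["dDTR"]]),
      pct_R = unname(pct[["dR"]]), pct_S = unname(pct[["dS"]]),
      n_pairs = nrow(diffs),
      r2 = if (sm$sigma < 1e-12) 1 else sm$r.squared,
      avg_yield = avg_yield,
      data = diffs
    ),
    class = "delta_fit"
  )
}

#' @export
print.delta_fit <- function(x, ...) {
  cat("<delta_fit>\n")
  cat(sprintf("  n_pairs = %d, R2 = %.3f, avg yield = %.0f kg/ha\n",
              x$n_pairs, x$r2, x$avg_yield))
  for (v in climate_vars) {
    cat(sprintf("  beta_%-3s = %10.3f kg/ha per unit  (%.2f%% per unit)\n",
                v, x[[paste0("beta_", v)]], x[[paste0("pct_", v)]]))
  }
  invisible(x)
}

#' Percent coefficients of a fitted first-difference regression
#'
#' Normalizes absolute climate coefficients by a cultivar's average grain
#' yield: `pct_v = 100 * beta_v / avg_yield`, in percent of mean yield per
#' unit of the climate variable. The stored absolute coefficients remain the
#' unrounded source of truth.
#'
#' @param fit A `delta_fit`.
#' @param avg_yield Average grain yield (kg/ha, > 0); defaults to the value
#'   stored in the fit.
#' @return A tibble with columns `variable`, `beta`, `pct`.
#' @export
percent_coefficients <- function(fit, avg_yield = fit$avg_yield) {
  if (!inherits(fit, "delta_fit")) {
    stop_ricedelta("`fit` must be a delta_fit.", "argument")
  }
  check_number(avg_yield, "avg_yield")
  if (avg_yield <= 0) {
    stop_ricedelta("`avg_yield` must be positive.", "argument")
  }
  beta <- vapply(paste0("beta_", climate_vars), function(f) fit[[f]],
                 numeric(1))
  tibble(
    variable = climate_vars,
    beta = unname(beta),
    pct = unname(100 * beta / avg_yield)
  )
}

#' Fit the first-difference regression for every cultivar
#'
#' Builds first-difference sets with [build_first_differences()] and fits
#' [fit_delta_regression()] per cultivar-season. Cultivars with fewer than
#' `min_pairs` usable pairs are skipped and listed in the `skipped`
#' attribute of the result.
#'
#' @inheritParams build_first_differences
#' @inheritParams fit_delta_regression
#' @return A tibble with one row per fitted cultivar-season: `season`,
#'   `cultivar`, `n_pairs`, `avg_yield`, `beta0`, `beta_T` ... `beta_S`,
#'   `pct_T` ... `pct_S`, `r2`.
#' @export
regress_cultivars <- function(yields, climate, min_pairs = 6) {
  yields <- as_tibble(yields)
  check_columns(yields, c("cultivar", "season", "year", "yield"), "`yields`")
  diffs <- build_first_differences(yields, climate)
  avg <- yields |>
    group_by(.data$cultivar, .data$season) |>
    summarise(avg_yield = mean(.data$yield), .groups = "drop")
  keys <- dplyr::distinct(yields, .data$cultivar, .data$season)
  skipped <- character()
  rows <- purrr::pmap(keys, function(cultivar, season) {
    d <- diffs[diffs$cultivar == cultivar & diffs$season == season, ]
    a <- avg$avg_yield[avg$cultivar == cultivar & avg$season == season]
    fit <- tryCatch(
      fit_delta_regression(d, a, min_pairs = min_pairs),
      ricedelta_insufficient_data = function(e) NULL
    )
    if (is.null(fit)) {
      skipped <<- c(skipped, sprintf("%s (%s)", cultivar, season))
      return(NULL)
    }
    tibble(
      season = season, cultivar = cultivar,
      n_pairs = fit$n_pairs, avg_yield = a,
      beta0 = fit$beta0,
      beta_T = fit$beta_T, beta_DTR = fit$beta_DTR,
      beta_R = fit$beta_R, beta_S = fit$beta_S,
      pct_T = fit$pct_T, pct_DTR = fit$pct_DTR,
      pct_R = fit$pct_R, pct_S = fit$pct_S,
      r2 = fit$r2
    )
  })
  out <- bind_rows(rows) |> arrange(.data$season, .data$cultivar)
  attr(out, "skipped") <- skipped
  out
}
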