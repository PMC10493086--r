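#' Tidy a fitted climate trend
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`), plus
#'   the slope's p-value on the `year` row.
#' @exportS3Method generics::tidy
tidy.trend_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "year"),
    estimate = c(x$beta0, x$beta1),
    p.value = c(NA_real_, x$p_slope)
  )
}

#' @rdname tidy.trend_fit
#' @exportS3Method generics::glance
glance.trend_fit <- function(x, ...) {
  tibble(
    variable = x$variable, season = x$season,
    r.squared = x$r2, sigma = x$residual_sd,
    p.value = x$p_slope, nobs = x$n
  )
}

#' Tidy a fitted first-difference regression
#'
#' @param x A `delta_fit`.
#' @param ... Unused.
#' @return One row per term with the absolute coefficient (`estimate`,
#'   kg/ha per unit), its standard error, and the percent form
#'   (`pct_estimate`, % of average yield per unit; `NA` for the intercept).
#' @exportS3Method generics::tidy
tidy.delta_fit <- function(x, ...) {
  terms <- c("(Intercept)", paste0("d", climate_vars))
  est <- c(x$beta0, x$beta_T, x$beta_DTR, x$beta_R, x$beta_S)
  pct <- c(NA_real_, x$pct_T, x$pct_DTR, x$pct_R, x$pct_S)
  tibble(
    term = terms,
    estimate = est,
    std.error = unname(x$se[terms]),
    pct_estimate = pct
  )
}

#' @rdname tidy.delta_fit
#' @exportS3Method generics::glance
glance.delta_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n_pairs, avg_yield = x$avg_yield)
}

#' Tidy a correlation matrix into long form
#'
#' @param x A `cor_matrix`.
#' @param ... Unused.
#' @return A long tibble of the lower triangle: `season`, `var_a`, `var_b`,
#'   `r`, `n`, `marker`.
#' @exportS3Method generics::tidy
tidy.cor_matrix <- function(x, ...) {
  pairs <- utils::combn(x$labels, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    tibble(
      season = x$season, var_a = pr[1], var_b = pr[2],
      r = x$r[pr[1], pr[2]], n = x$n[pr[1], pr[2]],
      marker = x$marker[pr[1], pr[2]]
    )
  }))
}
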