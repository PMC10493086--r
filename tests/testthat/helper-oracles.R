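# Independent closed-form oracles used to cross-check the model fits.

# Simple-regression slope/intercept from the textbook sum formulas.
ols_oracle <- function(t, x) {
  tb <- mean(t)
  xb <- mean(x)
  slope <- sum((t - tb) * (x - xb)) / sum((t - tb)^2)
  c(intercept = xb - slope * tb, slope = slope)
}

# Multiple-regression coefficients by brute-force normal equations.
normal_eq_oracle <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Pearson r from the raw sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Seasonal climate table from a clean synthetic weather series.
make_climate <- function(start, end, seed = 1, ...) {
  sc <- weather_scenario(start_year = start, end_year = end,
                         missing_rate = 0, seed = seed, ...)
  seasonal_climate(synth_weather(sc))
}

# A random full-rank first-difference set.
random_diffs <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    dY = rnorm(n, 0, 100), dT = rnorm(n), dDTR = rnorm(n),
    dR = rnorm(n, 0, 50), dS = rnorm(n, 0, 20)
  ))
}

# One-cultivar noise-free yield scenario with known coefficients.
known_cultivar <- function(first, last, season = "cool",
                           intercept = 5000, tech_trend = 25,
                           beta_T = 50, beta_DTR = -30, beta_R = 0.5,
                           beta_S = 1.2, noise_sd = 0) {
  tibble::tibble(
    id = "CV1", season = season, first_year = first, last_year = last,
    intercept = intercept, tech_trend = tech_trend,
    beta_T = beta_T, beta_DTR = beta_DTR, beta_R = beta_R, beta_S = beta_S,
    noise_sd = noise_sd
  )
}
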