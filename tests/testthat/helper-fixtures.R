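# Small fixtures shared across tests, all built in code.

fix_exposure_spec <- function(center = 15, boundary = c(0, 30),
                              degree = 2L, knots = c(10, 20)) {
  basis_spec("bspline", degree = degree, internal_knots = knots,
             boundary = boundary, center_value = center)
}

fix_lag_spec <- function(lag_low = 0L, lag_high = 10L, n_knots = 2L) {
  basis_spec("natural_cubic",
             internal_knots = log_spaced_lag_knots(lag_low, lag_high, n_knots),
             boundary = c(lag_low, lag_high), intercept = TRUE)
}

# A fitted_association with random (but reproducible) small coefficients;
# zero covariance unless asked otherwise.
fix_fit <- function(seed = 1, sd = 0.01, lag_low = 0L, lag_high = 10L,
                    exposure_spec = fix_exposure_spec(),
                    lag_spec = fix_lag_spec(lag_low, lag_high),
                    vcov_scale = 0) {
  p <- n_basis(exposure_spec) * n_basis(lag_spec)
  eta <- withr::with_seed(seed, stats::rnorm(p, 0, sd))
  V <- if (vcov_scale > 0) {
    A <- withr::with_seed(seed + 1, matrix(stats::rnorm(p * p), p))
    vcov_scale * crossprod(A) / p
  } else matrix(0, p, p)
  load_external_fit(eta, V, exposure_spec, lag_spec,
                    lag_window(lag_low, lag_high))
}

# A short random series with counts, exposures inside (0, 30).
fix_series <- function(n = 60, seed = 2, base_count = 100) {
  withr::with_seed(seed, {
    x <- pmin(pmax(15 + cumsum(stats::rnorm(n, 0, 2)) * 0.3 +
                     stats::rnorm(n, 0, 3), 0.2), 29.8)
    counts <- stats::rpois(n, base_count)
    exposure_series(seq(as.Date("2001-06-01"), by = "day", length.out = n),
                    x, counts)
  })
}

# Surface with protective late lags (harvesting-like lag structure).
fix_harvesting_surface <- function(x0 = 20, window = lag_window(0L, 15L)) {
  true_surface(
    f = function(x) 0.004 * pmax(x - x0, 0)^2,
    w = function(lag) exp(-lag / 2) - 0.45 * exp(-((lag - 8) / 3)^2),
    x0 = x0, window = window
  )
}
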