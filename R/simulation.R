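#' Known exposure-lag-response surface for simulation
#'
#' Defines the true bivariate function \eqn{g(x, \ell)} on the log-rate
#' scale from which synthetic series are generated, either directly or as a
#' separable product \eqn{f(x) w(\ell)}. The surface must vanish at its
#' reference exposure `x0` for every lag (checked numerically), so that
#' simulated risks are contrasts against the same counterfactual the
#' attribution machinery uses.
#'
#' @param f exposure-response function with `f(x0) = 0` (used with `w`).
#' @param w lag-response weight function over the window (used with `f`).
#' @param g bivariate function `g(x, lag)`, alternative to `f`/`w`;
#'   must be vectorised in `x` for scalar `lag`.
#' @param x0 reference exposure at which the surface is zero.
#' @param window a [lag_window()].
#' @return An object of class `true_surface` with elements `g`, `x0`,
#'   `window`.
#' @export
true_surface <- function(f = NULL, w = NULL, g = NULL, x0, window) {
  stopifnot(inherits(window, "lag_window"))
  if (is.null(g)) {
    if (is.null(f) || is.null(w)) stop("supply either 'g' or both 'f' and 'w'")
    force(f); force(w)
    g <- function(x, lag) f(x) * w(lag)
  }
  lags <- lags_of(window)
  at0 <- vapply(lags, function(l) g(x0, l), numeric(1))
  if (any(abs(at0) > 1e-10))
    stop("surface must vanish at x0 = ", x0, " for every lag; max |g(x0, l)| = ",
         signif(max(abs(at0)), 3))
  structure(list(g = g, x0 = x0, window = window), class = "true_surface")
}

#' Default U-shaped-by-decaying-lag surface
#'
#' A quadratic exposure-response \eqn{f(x) = c (x - x_0)^2} times
#' exponentially decaying lag weights \eqn{w(\ell) = e^{-\ell/\theta}}: the
#' simplest surface with the qualitative shape of temperature-mortality
#' associations (risk rising away from an optimum, effects fading with lag)
#' and closed-form truth everywhere.
#'
#' @param x0 minimum-risk exposure (default 20, a typical optimum in degrees
#'   Celsius).
#' @param scale curvature `c` of the quadratic, per squared exposure unit
#'   (default 2e-4, giving a cumulative RR of about 1.3 at 15 units from
#'   the optimum over lags 0-25).
#' @param decay lag e-folding time \eqn{\theta} in days (default 5).
#' @param window a [lag_window()] (default lags 0-25).
#' @return A `true_surface`.
#' @export
u_shaped_surface <- function(x0 = 20, scale = 2e-4, decay = 5,
                             window = lag_window(0L, 25L)) {
  true_surface(f = function(x) scale * (x - x0)^2,
               w = function(lag) exp(-lag / decay),
               x0 = x0, window = window)
}

#' Configuration for the synthetic daily series generator
#'
#' Describes the stochastic environment the generator emulates: a seasonal
#' exposure (annual sinusoid plus first-order autoregressive noise, the
#' standard reduced model of daily temperature), a seasonal baseline event
#' rate (winter-peaking, as daily all-cause mortality is), and overdispersed
#' counts.
#'
#' @param n_days length of the series (must exceed the lag window).
#' @param seed integer seed; the generator is deterministic given it.
#' @param baseline_log_rate annual-mean log event rate (default `log(150)`,
#'   about 150 events/day, the order of a large city's daily mortality), or
#'   a function of the day index returning the full baseline.
#' @param baseline_amplitude amplitude (log scale) of the winter-peaking
#'   seasonal baseline component (default 0.1, ignored when
#'   `baseline_log_rate` is a function).
#' @param exposure_mean annual mean exposure (default 15).
#' @param exposure_amplitude seasonal exposure amplitude, peaking in
#'   mid-July (default 8).
#' @param exposure_rho lag-1 autocorrelation of the exposure noise
#'   (default 0.8).
#' @param exposure_sd innovation standard deviation of the exposure noise
#'   (default 2; stationary sd `exposure_sd / sqrt(1 - rho^2)`).
#' @param overdispersion variance inflation factor `>= 1`; counts are
#'   Poisson at 1 and negative binomial with variance
#'   `overdispersion * mean` above 1 (default 1.2).
#' @param start first calendar date (default 2000-01-01, so the day index
#'   aligns with the calendar seasons).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_days, seed,
                              baseline_log_rate = log(150),
                              baseline_amplitude = 0.1,
                              exposure_mean = 15,
                              exposure_amplitude = 8,
                              exposure_rho = 0.8,
                              exposure_sd = 2,
                              overdispersion = 1.2,
                              start = as.Date("2000-01-01")) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 2L) stop("'n_days' must be >= 2")
  if (!is.function(baseline_log_rate) && !is.finite(baseline_log_rate))
    stop("'baseline_log_rate' must be finite or a function of the day index")
  if (overdispersion < 1) stop("'overdispersion' must be >= 1")
  if (abs(exposure_rho) >= 1) stop("'exposure_rho' must be in (-1, 1)")
  structure(
    list(n_days = n_days, seed = as.integer(seed),
         baseline_log_rate = baseline_log_rate,
         baseline_amplitude = baseline_amplitude,
         exposure_mean = exposure_mean,
         exposure_amplitude = exposure_amplitude,
         exposure_rho = exposure_rho, exposure_sd = exposure_sd,
         overdispersion = overdispersion, start = as.Date(start)),
    class = "simulation_config"
  )
}

surface_lag_sums <- function(surface, x) {
  # cumulated true contribution sum_l g(x_{t-l}, l); exposures before the
  # series start are taken at x0 (zero contribution)
  lags <- lags_of(surface$window)
  Q <- build_lag_matrix(x, surface$window)
  out <- numeric(length(x))
  for (j in seq_along(lags)) {
    gj <- surface$g(Q[, j], lags[j])
    gj[is.na(gj)] <- 0
    out <- out + gj
  }
  out
}

#' Simulate a daily exposure/count series from a known surface
#'
#' Generates exposures from the configured seasonal + AR(1) process and
#' counts from the log-linear model
#' \eqn{\log \mu_t = baseline_t + \sum_\ell g(x_{t-\ell}, \ell)}, with
#' Poisson or negative-binomial (variance = overdispersion x mean) noise.
#' Exposures before the series start are treated as held at the surface's
#' reference `x0`, contributing zero, so early-day rates are partial-history
#' rates (those days are dropped in complete-case fitting anyway).
#'
#' @param surface a [true_surface()].
#' @param config a [simulation_config()].
#' @return An [exposure_series()] with counts.
#' @export
simulate_series <- function(surface, config) {
  stopifnot(inherits(surface, "true_surface"),
            inherits(config, "simulation_config"))
  if (config$n_days <= surface$window$lag_high)
    stop("'n_days' must exceed the lag window (", surface$window$lag_high, ")")
  set.seed(config$seed)
  m <- config$n_days
  tt <- seq_len(m)
  mu_x <- config$exposure_mean +
    config$exposure_amplitude * cos(2 * pi * (tt - 196) / 365.25)
  innov <- stats::rnorm(m, 0, config$exposure_sd)
  e <- numeric(m)
  e[1L] <- stats::rnorm(1, 0, config$exposure_sd /
                          sqrt(1 - config$exposure_rho^2))
  for (t in seq_len(m - 1L))
    e[t + 1L] <- config$exposure_rho * e[t] + innov[t + 1L]
  x <- mu_x + e
  baseline <- if (is.function(config$baseline_log_rate)) {
    config$baseline_log_rate(tt)
  } else {
    config$baseline_log_rate +
      config$baseline_amplitude * cos(2 * pi * (tt - 15) / 365.25)
  }
  log_rate <- baseline + surface_lag_sums(surface, x)
  if (max(log_rate) > log(1e7))
    stop("event rate overflow (max log rate ", signif(max(log_rate), 4),
         "); use a smaller surface magnitude or baseline")
  rate <- exp(log_rate)
  counts <- if (config$overdispersion == 1) {
    stats::rpois(m, rate)
  } else {
    stats::rnbinom(m, mu = rate, size = rate / (config$overdispersion - 1))
  }
  exposure_series(seq(config$start, by = "day", length.out = m), x, counts)
}

#' Brute-force true attributable burden under a known surface
#'
#' Ground truth for recovery tests: applies the backward attribution
#' formulas with the estimated contributions replaced by the true surface
#' \eqn{g}, day by day, and totals over the days with complete lag history.
#'
#' @param surface a [true_surface()].
#' @param series an [exposure_series()] with counts (typically from
#'   [simulate_series()] under the same surface).
#' @param range an [exposure_range()] or `NULL` for overall.
#' @return Named numeric vector `c(an_tot, af_tot)`.
#' @export
true_total_attribution <- function(surface, series, range = NULL) {
  stopifnot(inherits(surface, "true_surface"),
            inherits(series, "exposure_series"))
  if (is.null(series$count)) stop("'series' must carry counts")
  x <- series$exposure
  m <- length(x)
  L <- surface$window$lag_high
  lags <- lags_of(surface$window)
  sel <- in_range(x, range)
  bsum <- rep(NA_real_, m)
  for (t in (L + 1L):m) {
    past <- x[t - lags]
    contrib <- mapply(surface$g, past, lags)
    bsum[t] <- sum(contrib[sel[t - lags]])
  }
  af <- 1 - exp(-bsum)
  an <- af * series$count
  keep <- !is.na(an)
  an_tot <- sum(an[keep])
  c(an_tot = an_tot, af_tot = an_tot / sum(series$count[keep]))
}
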