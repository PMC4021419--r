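#' Attributable fraction from a cumulated log-risk contrast
#'
#' The defining transform of attributable-risk measures:
#' \eqn{AF = 1 - \exp(-\beta)}, with \eqn{\beta} the cumulated log relative
#' risk of the observed exposure (history) versus the counterfactual
#' reference. For a binary exposure this reduces to the familiar
#' \eqn{(RR - 1)/RR}. A negative \eqn{\beta} yields a negative fraction,
#' which is meaningful (a protective history relative to the reference) and
#' is never truncated.
#'
#' @param beta_sum finite numeric vector of cumulated log-risk contrasts.
#' @return `1 - exp(-beta_sum)`, always strictly below 1.
#' @export
#' @examples
#' attributable_fraction(log(2))   # RR = 2  ->  AF = 0.5
attributable_fraction <- function(beta_sum) {
  if (any(!is.finite(beta_sum)))
    stop("'beta_sum' must be finite")
  1 - exp(-beta_sum)
}

#' Joint attributable fraction for multiple exposure contributions
#'
#' Combines independent log-risk contributions multiplicatively:
#' \eqn{AF_{x_1,\ldots,x_p} = 1 - \exp(-\sum_i \beta_{x_i})
#' = 1 - \prod_i (1 - AF_{x_i})}. For non-negative contributions the joint
#' fraction never exceeds the sum of the individual ones — summing
#' separately-computed fractions over-counts the shared cases.
#'
#' @param beta_sums finite numeric vector of per-exposure log-risk
#'   contrasts; an empty vector gives 0.
#' @return A single joint attributable fraction.
#' @export
joint_attributable_fraction <- function(beta_sums) {
  if (length(beta_sums) == 0L) return(0)
  if (any(!is.finite(beta_sums))) stop("'beta_sums' must be finite")
  1 - exp(-sum(beta_sums))
}

#' Exposure range for separating attributable components
#'
#' A range \eqn{r = [l, h]} selecting the exposure values whose risk
#' contributions are attributed. Infinite bounds are allowed; `"overall"`
#' (a `NULL` range everywhere in this package) means no restriction. The
#' closure says which endpoints belong to the range; when ranges split at
#' the reference \eqn{x_0} the choice is numerically immaterial, since the
#' contribution at \eqn{x_0} is exactly zero.
#'
#' @param low,high numeric bounds, `low < high` (`-Inf`/`Inf` allowed).
#' @param label short text label (used in outputs).
#' @param closure one of `"(]"`, `"[)"`, `"[]"`, `"()"`.
#' @return An object of class `exposure_range`.
#' @export
exposure_range <- function(low, high, label = NULL,
                           closure = c("(]", "[)", "[]", "()")) {
  closure <- match.arg(closure)
  if (!is.numeric(low) || !is.numeric(high) || is.na(low) || is.na(high))
    stop("'low' and 'high' must be numeric (Inf allowed)")
  if (low >= high) stop("'low' must be strictly below 'high'")
  if (is.null(label))
    label <- paste0(substr(closure, 1, 1), signif(low, 6), ", ",
                    signif(high, 6), substr(closure, 2, 2))
  structure(list(low = as.numeric(low), high = as.numeric(high),
                 label = as.character(label), closure = closure),
            class = "exposure_range")
}

in_range <- function(x, range) {
  if (is.null(range)) return(rep(TRUE, length(x)))
  lo <- switch(substr(range$closure, 1, 1),
               "(" = x > range$low, "[" = x >= range$low)
  hi <- switch(substr(range$closure, 2, 2),
               ")" = x < range$high, "]" = x <= range$high)
  lo & hi
}

range_label <- function(range) if (is.null(range)) "overall" else range$label

#' Default cold/heat and mild/extreme exposure ranges
#'
#' Splits the exposure axis at the reference `x0` into cold (below) and heat
#' (above) components and, optionally, further into mild and extreme parts
#' at the given percentiles of the observed exposure distribution (defaults:
#' 1st and 99th, the conventional extreme-temperature cut-offs). Extreme
#' ranges are closed at the cut-off.
#'
#' @param exposure observed exposure values (for the percentile cut-offs).
#' @param x0 the reference (minimum-risk) exposure splitting cold from heat.
#' @param percentiles length-2 probabilities for the extreme cut-offs, or
#'   `NULL` for the plain cold/heat split.
#' @return Named list of [exposure_range()] objects.
#' @export
standard_ranges <- function(exposure, x0, percentiles = c(0.01, 0.99)) {
  cold <- exposure_range(-Inf, x0, "cold", closure = "()")
  heat <- exposure_range(x0, Inf, "heat", closure = "()")
  out <- list(cold = cold, heat = heat)
  if (!is.null(percentiles)) {
    q <- stats::quantile(exposure, percentiles, na.rm = TRUE, names = FALSE)
    if (!(q[1L] < x0 && x0 < q[2L]))
      stop("percentile cut-offs (", signif(q[1L], 4), ", ", signif(q[2L], 4),
           ") must bracket x0 = ", signif(x0, 4))
    out$extreme_cold <- exposure_range(-Inf, q[1L], "extreme cold",
                                       closure = "(]")
    out$mild_cold <- exposure_range(q[1L], x0, "mild cold", closure = "()")
    out$mild_heat <- exposure_range(x0, q[2L], "mild heat", closure = "()")
    out$extreme_heat <- exposure_range(q[2L], Inf, "extreme heat",
                                       closure = "[)")
  }
  out
}

new_attribution_series <- function(series, af, an, perspective, range) {
  out <- data.frame(date = series$date, exposure = series$exposure,
                    count = series$count, af = af, an = an)
  attr(out, "perspective") <- perspective
  attr(out, "range") <- range
  attr(out, "range_label") <- range_label(range)
  class(out) <- c("attribution_series", "data.frame")
  out
}

# beta_{x_t, l} for every observation and lag: m x nl matrix.
beta_by_obs_lag <- function(x, fit) {
  lags <- lags_of(fit$window)
  B <- basis_rows(x, fit$exposure_spec)
  W <- basis_rows(lags, fit$lag_spec)
  B %*% eta_matrix(fit) %*% t(W)
}

#' Backward attributable fraction and number
#'
#' For each day \eqn{t} with complete lag history, attributes the current
#' cases to the exposures experienced over the preceding lag window:
#' \deqn{bAF_t = 1 - \exp\Big(-\sum_{\ell=\ell_0}^{L}
#'   I(x_{t-\ell} \in r)\, \beta_{x_{t-\ell},\ell}\Big), \qquad
#'   bAN_t = bAF_t \cdot n_t,}
#' versus the counterfactual of a constant exposure \eqn{x_0} throughout the
#' window. The first `lag_high` days, and days whose window contains a
#' missing exposure, are `NA`. Components for disjoint ranges are
#' sub-additive (they share the exponential), and daily values can be
#' negative under harvesting-like lag structures.
#'
#' @param series an [exposure_series()] with counts.
#' @param fit a `fitted_association`.
#' @param range an [exposure_range()] restricting which past exposures
#'   contribute, or `NULL` for the overall measure.
#' @return An `attribution_series` data frame with columns `date`,
#'   `exposure`, `count`, `af`, `an`.
#' @export
backward_attribution <- function(series, fit, range = NULL) {
  stopifnot(inherits(series, "exposure_series"),
            inherits(fit, "fitted_association"))
  if (is.null(series$count)) stop("'series' must carry counts")
  if (!is.null(range)) stopifnot(inherits(range, "exposure_range"))
  x <- series$exposure
  m <- length(x)
  if (m < fit$window$lag_high + 1L)
    stop("series shorter than the lag window: no complete day exists")
  M <- beta_by_obs_lag(x, fit)               # beta_{x_t, l}
  sel <- as.numeric(in_range(x, range))
  sel[is.na(x)] <- NA_real_
  lags <- lags_of(fit$window)
  bsum <- numeric(m)
  for (j in seq_along(lags)) {
    l <- lags[j]
    contrib <- M[, j] * sel                  # I(x in r) * beta_{x, l}
    shifted <- if (l == 0L) contrib else
      c(rep(NA_real_, l), contrib[seq_len(m - l)])
    bsum <- bsum + shifted
  }
  af <- 1 - exp(-bsum)
  an <- af * series$count
  new_attribution_series(series, af, an, "backward", range)
}

#' Forward attributable fraction and number
#'
#' Attributes future cases to today's exposure: for each day \eqn{t},
#' \deqn{fAF_t = 1 - \exp\Big(-\sum_{\ell=\ell_0}^{L}
#'   \beta_{x_t,\ell}\Big) \cdot I(x_t \in r), \qquad
#'   fAN_t = fAF_t \cdot \frac{\sum_\ell n_{t+\ell}}{L - \ell_0 + 1}.}
#' The fraction needs only the overall cumulative association at \eqn{x_t},
#' so a reduced exposure-response curve (e.g. from a multi-site pooled
#' analysis) suffices: pass a function mapping exposure to cumulative
#' log-RR in place of the fit. Averaging the future counts only
#' approximates the lag structure, which makes forward totals mildly
#' conservative relative to backward ones; component fractions for disjoint
#' ranges are exactly additive.
#'
#' At the series tail, fewer than \eqn{L - \ell_0 + 1} future counts exist:
#' with `tail = "truncate"` (default) the available counts are averaged
#' (divisor reduced accordingly); with `tail = "missing"` such days are `NA`.
#'
#' @param series an [exposure_series()] with counts.
#' @param fit a `fitted_association`, or a function `x -> cumulative log-RR`
#'   (in which case `window` must be supplied).
#' @param range an [exposure_range()] or `NULL` for overall.
#' @param tail handling of days with an incomplete forward count window.
#' @param window required when `fit` is a plain curve function.
#' @return An `attribution_series` data frame.
#' @export
forward_attribution <- function(series, fit, range = NULL,
                                tail = c("truncate", "missing"),
                                window = NULL) {
  stopifnot(inherits(series, "exposure_series"))
  tail <- match.arg(tail)
  if (is.null(series$count)) stop("'series' must carry counts")
  if (!is.null(range)) stopifnot(inherits(range, "exposure_range"))
  x <- series$exposure
  m <- length(x)
  if (inherits(fit, "fitted_association")) {
    window <- fit$window
    cum <- rowSums(beta_by_obs_lag(x, fit))
  } else if (is.function(fit)) {
    if (is.null(window)) stop("'window' is required with a curve function")
    stopifnot(inherits(window, "lag_window"))
    cum <- rep(NA_real_, m)
    ok <- is.finite(x)
    cum[ok] <- fit(x[ok])
  } else stop("'fit' must be a fitted_association or a function")
  sel <- as.numeric(in_range(x, range))
  sel[is.na(x)] <- NA_real_
  af <- (1 - exp(-cum)) * sel
  # mean of counts over the forward window t + lag_low .. t + lag_high
  n <- series$count
  lags <- lags_of(window)
  acc <- matrix(NA_real_, m, length(lags))
  for (j in seq_along(lags)) {
    l <- lags[j]
    acc[, j] <- if (l == 0L) n else c(n[-seq_len(l)], rep(NA_real_, l))
  }
  avail <- rowSums(!is.na(acc))
  fmean <- rowSums(acc, na.rm = TRUE) / avail
  fmean[avail == 0L] <- NA_real_
  if (tail == "missing") fmean[avail < length(lags)] <- NA_real_
  an <- af * fmean
  new_attribution_series(series, af, an, "forward", range)
}

#' Total attributable number and fraction
#'
#' Aggregates a daily attribution series:
#' \eqn{AN_{tot} = \sum_t AN_t} and \eqn{AF_{tot} = AN_{tot} / \sum_t n_t},
#' both sums running over the days with a non-missing attributable number
#' (so the incomplete-history days excluded from the daily measures are also
#' excluded from the denominator).
#'
#' @param daily an `attribution_series`.
#' @return An `attribution_summary` (point estimates only; see
#'   [montecarlo_eci()] for interval estimates).
#' @export
total_attribution <- function(daily) {
  stopifnot(inherits(daily, "attribution_series"))
  keep <- !is.na(daily$an) & !is.na(daily$count)
  ntot <- sum(daily$count[keep])
  if (!any(keep) || ntot <= 0)
    stop("no contributing days with positive total counts")
  an_total <- sum(daily$an[keep])
  new_attribution_summary(
    an_total = an_total, af_total = an_total / ntot,
    total_counts = ntot, n_days = sum(keep),
    perspective = attr(daily, "perspective", exact = TRUE),
    range = attr(daily, "range", exact = TRUE)
  )
}

new_attribution_summary <- function(an_total, af_total, total_counts, n_days,
                                    perspective, range, eci_an = NULL,
                                    eci_af = NULL, n_sim = NA_integer_,
                                    seed = NA_integer_) {
  structure(
    list(an_total = an_total, af_total = af_total,
         total_counts = total_counts, n_days = n_days,
         perspective = perspective, range = range,
         range_label = range_label(range),
         eci_an = eci_an, eci_af = eci_af, n_sim = n_sim, seed = seed),
    class = "attribution_summary"
  )
}

#' @export
print.attribution_summary <- function(x, digits = 4, ...) {
  cat("<attribution_summary> ", x$perspective, ", range: ", x$range_label,
      "\n  AN total: ", signif(x$an_total, digits),
      if (!is.null(x$eci_an))
        paste0(" (95% eCI ", signif(x$eci_an[1L], digits), " to ",
               signif(x$eci_an[2L], digits), ")"),
      "\n  AF total: ", signif(x$af_total, digits),
      if (!is.null(x$eci_af))
        paste0(" (95% eCI ", signif(x$eci_af[1L], digits), " to ",
               signif(x$eci_af[2L], digits), ")"),
      "\n  over ", x$n_days, " days, ", x$total_counts, " cases",
      if (!is.na(x$n_sim)) paste0("; ", x$n_sim, " MC draws, seed ", x$seed),
      "\n", sep = "")
  invisible(x)
}

# Linear map Z with beta_sum = Z %*% eta for the requested perspective and
# range, plus the case weights that turn daily AFs into daily ANs. Totals
# are then AN_tot(eta) = sum(w * (1 - exp(-Z eta))) over contributing days,
# evaluated for many eta draws at once.
attribution_operator <- function(series, fit, range, perspective,
                                 tail = "truncate") {
  x <- series$exposure
  m <- length(x)
  lags <- lags_of(fit$window)
  B <- basis_rows(x, fit$exposure_spec)
  W <- basis_rows(lags, fit$lag_spec)
  vx <- ncol(B); vl <- ncol(W)
  sel <- as.numeric(in_range(x, range))
  sel[is.na(x)] <- NA_real_
  if (perspective == "backward") {
    Z <- matrix(0, m, vx * vl)
    for (j in seq_along(lags)) {
      l <- lags[j]
      contrib <- (B * sel)[, rep(seq_len(vx), each = vl), drop = FALSE] *
        matrix(rep(W[j, ], vx), m, vx * vl, byrow = TRUE)
      Z <- Z + if (l == 0L) contrib else
        rbind(matrix(NA_real_, l, vx * vl),
              contrib[seq_len(m - l), , drop = FALSE])
    }
    weights <- series$count
  } else {
    wsum <- colSums(W)                       # lag basis summed over the window
    Z <- (B * sel)[, rep(seq_len(vx), each = vl), drop = FALSE] *
      matrix(rep(wsum, vx), m, vx * vl, byrow = TRUE)
    n <- series$count
    acc <- matrix(NA_real_, m, length(lags))
    for (j in seq_along(lags)) {
      l <- lags[j]
      acc[, j] <- if (l == 0L) n else c(n[-seq_len(l)], rep(NA_real_, l))
    }
    avail <- rowSums(!is.na(acc))
    weights <- rowSums(acc, na.rm = TRUE) / avail
    weights[avail == 0L] <- NA_real_
    if (tail == "missing") weights[avail < length(lags)] <- NA_real_
  }
  keep <- !is.na(weights) & !is.na(rowSums(Z))
  list(Z = Z[keep, , drop = FALSE], weights = weights[keep],
       total_counts = sum(series$count[keep]), n_days = sum(keep))
}

#' Empirical confidence intervals by Monte Carlo coefficient resampling
#'
#' Quantifies the uncertainty of total attributable numbers and fractions by
#' resampling the cross-basis coefficients from their estimated sampling
#' distribution: draws \eqn{\eta^{(j)} \sim MVN(\hat\eta, V(\hat\eta))},
#' \eqn{j = 1, \ldots, n_{sim}}, recomputes the total for every draw, and
#' reports the 2.5th and 97.5th percentiles as the 95% empirical confidence
#' interval (eCI). The default of 5000 draws is the conventional choice;
#' results are deterministic given `seed`.
#'
#' @param series an [exposure_series()] with counts.
#' @param fit a `fitted_association` with a valid covariance.
#' @param range an [exposure_range()] or `NULL` for overall.
#' @param perspective `"backward"` or `"forward"`.
#' @param n_sim number of Monte Carlo draws (>= 1).
#' @param seed integer seed for the draws.
#' @param tail forward-window tail handling, as in [forward_attribution()].
#' @return An `attribution_summary` with point estimates and `eci_an`,
#'   `eci_af` interval bounds.
#' @export
montecarlo_eci <- function(series, fit, range = NULL,
                           perspective = c("backward", "forward"),
                           n_sim = 5000L, seed = 1L,
                           tail = c("truncate", "missing")) {
  stopifnot(inherits(series, "exposure_series"),
            inherits(fit, "fitted_association"))
  perspective <- match.arg(perspective)
  tail <- match.arg(tail)
  n_sim <- as.integer(n_sim)
  if (is.na(n_sim) || n_sim < 1L) stop("'n_sim' must be >= 1")
  V <- fit$vcov
  asym <- max(abs(V - t(V)))
  if (asym > 1e-8 * max(1, max(abs(V))))
    stop("covariance is not symmetric (max asymmetry ", signif(asym, 3), ")")
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, abs(max(ev))))
    stop("covariance is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  op <- attribution_operator(series, fit, range, perspective, tail)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  draws <- MASS::mvrnorm(n_sim, mu = fit$eta_hat, Sigma = V, tol = 1e-6)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  if (n_sim == 1L) draws <- matrix(draws, nrow = 1L)
  # AN_tot per draw: column j of 1 - exp(-Z eta_j), weighted by cases; the
  # point estimate goes through the same product so a degenerate covariance
  # yields an interval exactly equal to it
  S <- op$Z %*% cbind(fit$eta_hat, t(draws))           # days x (1 + n_sim)
  totals <- colSums(op$weights * (1 - exp(-S)))
  an_sims <- totals[-1L]
  af_sims <- an_sims / op$total_counts
  new_attribution_summary(
    an_total = unname(totals[1L]), af_total = unname(totals[1L]) / op$total_counts,
    total_counts = op$total_counts, n_days = op$n_days,
    perspective = perspective, range = range,
    eci_an = stats::quantile(an_sims, c(0.025, 0.975), names = FALSE),
    eci_af = stats::quantile(af_sims, c(0.025, 0.975), names = FALSE),
    n_sim = n_sim, seed = as.integer(seed)
  )
}
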