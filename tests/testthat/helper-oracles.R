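# Independent oracles, deliberately naive: a Cox-de Boor recursion for
# B-splines and brute-force double loops for cross-basis rows and daily
# attributable fractions. They share no code with the implementation.

# All basis functions of order degree+1 on the clamped knot vector; columns
# ordered as the recursion produces them (first function dropped when
# intercept = FALSE, matching the package's B-spline convention).
coxdeboor_bspline <- function(x, degree, internal_knots, boundary,
                              intercept = TRUE) {
  ord <- degree + 1L
  knots <- c(rep(boundary[1L], ord), internal_knots, rep(boundary[2L], ord))
  nb <- length(internal_knots) + ord
  basis_one <- function(xx, i, d) {
    if (d == 0L) {
      # right-closed last interval so the basis sums to 1 at the boundary
      if (knots[i] <= xx && (xx < knots[i + 1L] ||
                             (xx == boundary[2L] && knots[i + 1L] >= boundary[2L] &&
                              knots[i] < boundary[2L])))
        1 else 0
    } else {
      a <- if (knots[i + d] > knots[i])
        (xx - knots[i]) / (knots[i + d] - knots[i]) *
          basis_one(xx, i, d - 1L) else 0
      b <- if (knots[i + d + 1L] > knots[i + 1L])
        (knots[i + d + 1L] - xx) / (knots[i + d + 1L] - knots[i + 1L]) *
          basis_one(xx, i + 1L, d - 1L) else 0
      a + b
    }
  }
  out <- t(vapply(x, function(xx)
    vapply(seq_len(nb), function(i) basis_one(xx, i, degree), numeric(1)),
    numeric(nb)))
  if (!intercept) out <- out[, -1L, drop = FALSE]
  out
}

# beta_{x, l} as an explicit bilinear form from single-point basis
# evaluations (eta in exposure-major order, lag index fastest).
brute_beta <- function(x, lag, eta, exposure_spec, lag_spec) {
  bx <- as.numeric(evaluate_basis(x, exposure_spec))
  wl <- as.numeric(evaluate_basis(lag, lag_spec))
  total <- 0
  vl <- length(wl)
  for (i in seq_along(bx))
    for (k in seq_along(wl))
      total <- total + bx[i] * eta[(i - 1L) * vl + k] * wl[k]
  total
}

# Daily backward AF by a plain double loop over days and lags.
brute_backward_af <- function(x, eta, exposure_spec, lag_spec, window,
                              range = NULL) {
  m <- length(x)
  lags <- window$lag_low:window$lag_high
  af <- rep(NA_real_, m)
  for (t in seq_len(m)) {
    if (t <= window$lag_high) next
    s <- 0
    for (l in lags) {
      xl <- x[t - l]
      if (is.null(range) || in_range_oracle(xl, range))
        s <- s + brute_beta(xl, l, eta, exposure_spec, lag_spec)
    }
    af[t] <- 1 - exp(-s)
  }
  af
}

# Daily forward AF: needs only the cumulative sum at the day's own exposure.
brute_forward_af <- function(x, eta, exposure_spec, lag_spec, window,
                             range = NULL) {
  lags <- window$lag_low:window$lag_high
  vapply(x, function(xx) {
    if (!is.null(range) && !in_range_oracle(xx, range)) return(0)
    s <- 0
    for (l in lags) s <- s + brute_beta(xx, l, eta, exposure_spec, lag_spec)
    1 - exp(-s)
  }, numeric(1))
}

in_range_oracle <- function(x, range) {
  lo <- if (substr(range$closure, 1, 1) == "(") x > range$low else x >= range$low
  hi <- if (substr(range$closure, 2, 2) == ")") x < range$high else x <= range$high
  lo && hi
}
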