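## From fitted cross-basis coefficients to interpretable effect summaries:
## the beta_{x,l} contribution grid, the overall cumulative association, and
## the minimum-risk exposure used as counterfactual reference.

eta_matrix <- function(fit) {
  vx <- n_basis(fit$exposure_spec)
  vl <- n_basis(fit$lag_spec)
  matrix(fit$eta_hat, vx, vl, byrow = TRUE)   # exposure-major coefficient order
}

check_exposure_range <- function(exposures, spec, extrapolate) {
  out <- exposures < spec$boundary[1L] | exposures > spec$boundary[2L]
  if (any(out)) {
    if (!extrapolate)
      stop(sum(out), " exposure value(s) outside the basis boundary [",
           spec$boundary[1L], ", ", spec$boundary[2L], "]")
    warning(sum(out), " exposure value(s) outside the basis boundary; ",
            "extrapolating per the basis rules")
  }
}

#' Grid of exposure-lag contributions
#'
#' Evaluates the fitted exposure-lag-response surface on a grid: entry
#' \eqn{(x, \ell)} is \eqn{\beta_{x,\ell}}, the log-rate contribution of
#' exposure \eqn{x} at lag \eqn{\ell} relative to the reference
#' \eqn{x_0}, computed as the bilinear form (centered exposure basis at
#' \eqn{x}) x (coefficient matrix) x (lag basis at \eqn{\ell}).
#'
#' @param fit a `fitted_association`.
#' @param exposures numeric vector of exposure values.
#' @param extrapolate allow exposures beyond the basis boundary (with a
#'   warning)? If `FALSE`, such values are an error.
#' @return A `beta_grid`: list with `exposures`, `lags`, the matrix `beta`
#'   (`length(exposures)` x number of lags) and `center_value`.
#' @export
beta_grid <- function(fit, exposures, extrapolate = TRUE) {
  stopifnot(inherits(fit, "fitted_association"))
  exposures <- as.numeric(exposures)
  if (any(!is.finite(exposures))) stop("'exposures' must be finite")
  check_exposure_range(exposures, fit$exposure_spec, extrapolate)
  lags <- lags_of(fit$window)
  B <- basis_rows(exposures, fit$exposure_spec)
  W <- basis_rows(lags, fit$lag_spec)
  beta <- B %*% eta_matrix(fit) %*% t(W)
  dimnames(beta) <- list(NULL, paste0("lag", lags))
  structure(list(exposures = exposures, lags = lags, beta = beta,
                 center_value = fit$center_value),
            class = "beta_grid")
}

#' Overall cumulative association
#'
#' The net log-risk of exposure \eqn{x} accumulated across the whole lag
#' window, \eqn{\sum_{\ell=\ell_0}^{L} \beta_{x,\ell}}; its exponential is
#' the overall cumulative relative risk. Equals the cross-basis row times the
#' coefficients for a series held constant at \eqn{x}.
#'
#' @inheritParams beta_grid
#' @param x numeric vector of exposure values.
#' @return Numeric vector, one cumulative log-RR contrast per element of `x`.
#' @export
overall_cumulative <- function(fit, x, extrapolate = TRUE) {
  unname(rowSums(beta_grid(fit, x, extrapolate = extrapolate)$beta))
}

#' Locate the minimum-risk exposure
#'
#' Searches a grid for the exposure value minimizing the overall cumulative
#' association — for temperature-mortality applications, the minimum
#' mortality temperature (MMT). That value is the natural counterfactual
#' reference \eqn{x_0}: re-centering there makes every contrast (and hence
#' every attributable measure) relative to the least-harmful exposure.
#'
#' @param fit a `fitted_association`.
#' @param search_grid optional numeric grid; defaults to the basis boundary
#'   range in steps of `step`.
#' @param step grid resolution when `search_grid` is not given.
#' @return The grid value with minimal overall cumulative association; on
#'   ties, the smallest such value (with a warning).
#' @seealso [recenter()]
#' @export
find_minimum_risk_exposure <- function(fit, search_grid = NULL, step = 0.1) {
  stopifnot(inherits(fit, "fitted_association"))
  if (is.null(search_grid)) {
    b <- fit$exposure_spec$boundary
    search_grid <- seq(b[1L], b[2L], by = step)
  }
  cum <- overall_cumulative(fit, search_grid)
  ties <- which(cum <= min(cum) + 1e-12)
  if (length(ties) > 1L)
    warning("flat overall cumulative curve: ", length(ties),
            " grid values tie for the minimum; returning the smallest")
  search_grid[ties[1L]]
}

#' Re-center a fitted association at a new reference exposure
#'
#' Changes the counterfactual reference \eqn{x_0} without refitting. Because
#' centering is implemented as subtraction of the basis row at \eqn{x_0},
#' the coefficients are unchanged and every contrast transforms exactly as
#' \eqn{\beta_x^* = \beta_x - \beta_{x_1}}; centering only shifts a constant
#' into the model intercept, so the fit itself is invariant.
#'
#' @param fit a `fitted_association`.
#' @param new_center new reference exposure, within the basis boundary.
#' @return The modified `fitted_association`.
#' @export
recenter <- function(fit, new_center) {
  stopifnot(inherits(fit, "fitted_association"))
  spec <- fit$exposure_spec
  spec$center_value <- NULL
  spec <- basis_spec(spec$kind,
                     degree = if (is.na(spec$degree)) 3L else spec$degree,
                     internal_knots = spec$internal_knots,
                     boundary = spec$boundary,
                     center_value = new_center,
                     intercept = spec$intercept)
  fit$exposure_spec <- spec
  fit$center_value <- new_center
  fit
}
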