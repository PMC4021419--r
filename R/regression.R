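#' Confounder design: seasonal spline and day-of-week indicators
#'
#' Standard time-series confounder control for daily environmental
#' epidemiology: a smooth natural cubic spline of the date index absorbing
#' seasonality and long-term trend, plus day-of-week indicator variables and
#' an intercept. The spline gets `round(df_per_year * n_years)` degrees of
#' freedom, with `n_years` the series length over 365.25.
#'
#' @param dates `Date` vector, consecutive days.
#' @param df_per_year degrees of freedom per year for the seasonal spline
#'   (default 10, the conventional choice for daily mortality series).
#' @param weekday_indicators include six day-of-week dummies (reference
#'   category dropped)?
#' @return Numeric matrix with an `(Intercept)` column, `time<j>` spline
#'   columns and, if requested, `dow<name>` columns.
#' @export
build_confounder_design <- function(dates, df_per_year = 10,
                                    weekday_indicators = TRUE) {
  dates <- as.Date(dates)
  m <- length(dates)
  if (m < 2L || any(diff(as.integer(dates)) != 1L))
    stop("'dates' must be consecutive days")
  df <- as.integer(round(df_per_year * m / 365.25))
  if (df < 1L) stop("'df_per_year' too small: seasonal spline needs >= 1 df")
  if (df >= m) stop("seasonal spline df (", df, ") must be below the number ",
                    "of observations (", m, ")")
  tt <- seq_len(m)
  S <- splines::ns(tt, df = df)
  colnames(S) <- paste0("time", seq_len(ncol(S)))
  out <- cbind(`(Intercept)` = 1, S)
  if (isTRUE(weekday_indicators)) {
    dow <- factor(format(dates, "%u"), levels = as.character(1:7))
    D <- stats::model.matrix(~dow)[, -1L, drop = FALSE]
    colnames(D) <- paste0("dow", 2:7)
    out <- cbind(out, D)
  }
  out
}

new_fitted_association <- function(eta_hat, vcov, dispersion, exposure_spec,
                                   lag_spec, window, n_used = NA_integer_) {
  structure(
    list(eta_hat = eta_hat, vcov = vcov, dispersion = dispersion,
         center_value = exposure_spec$center_value,
         exposure_spec = exposure_spec, lag_spec = lag_spec,
         window = window, n_used = n_used),
    class = "fitted_association"
  )
}

#' @export
print.fitted_association <- function(x, ...) {
  cat("<fitted_association> ", length(x$eta_hat), " cross-basis coefficients",
      ", lags ", x$window$lag_low, "-", x$window$lag_high,
      ", centered at ", signif(x$center_value, 6), "\n",
      "  dispersion: ", signif(x$dispersion, 4),
      if (!is.na(x$n_used)) paste0("  n used: ", x$n_used), "\n", sep = "")
  invisible(x)
}

#' Fit the overdispersed Poisson time-series model
#'
#' Fits `counts ~ crossbasis + confounders` by quasi-Poisson regression
#' (log link), the standard model for daily count series with exposure-lag
#' terms. Rows with incomplete lag history or missing values are dropped
#' (complete-case). The dispersion is the Pearson chi-square statistic over
#' the residual degrees of freedom, and the coefficient covariance is scaled
#' by it. Only the cross-basis coefficients and their covariance sub-block
#' are retained, which is all the attribution machinery needs.
#'
#' @param counts non-negative integer vector, one entry per series row.
#' @param crossbasis a [build_crossbasis()] matrix.
#' @param confounders numeric confounder design matrix (should contain the
#'   intercept), same number of rows.
#' @return A `fitted_association` with elements `eta_hat`, `vcov`,
#'   `dispersion`, `center_value`, the basis specs, the lag window and
#'   `n_used`.
#' @export
fit_quasipoisson <- function(counts, crossbasis, confounders) {
  stopifnot(inherits(crossbasis, "crossbasis"))
  counts <- as.numeric(counts)
  m <- nrow(crossbasis)
  if (length(counts) != m || nrow(confounders) != m)
    stop("'counts', 'crossbasis' and 'confounders' must have matching rows")
  if (any(counts < 0, na.rm = TRUE)) stop("'counts' must be non-negative")
  X <- cbind(confounders, unclass(crossbasis))
  keep <- stats::complete.cases(X) & !is.na(counts)
  if (sum(keep) <= ncol(X))
    stop("too few complete observations (", sum(keep), ") for ", ncol(X),
         " parameters")
  fit <- stats::glm.fit(X[keep, , drop = FALSE], counts[keep],
                        family = stats::quasipoisson())
  if (!fit$converged)
    stop("quasi-Poisson fit did not converge after ", fit$iter, " iterations")
  cf <- fit$coefficients
  if (anyNA(cf))
    stop("rank-deficient design: collinear column(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  # Pearson dispersion and dispersion-scaled covariance
  mu <- fit$fitted.values
  disp <- sum((fit$y - mu)^2 / mu) / fit$df.residual
  R <- fit$qr$qr[seq_len(fit$qr$rank), seq_len(fit$qr$rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  V <- chol2inv(R) * disp
  dimnames(V) <- list(names(cf), names(cf))
  idx <- seq.int(ncol(confounders) + 1L, ncol(X))
  new_fitted_association(
    eta_hat = cf[idx],
    vcov = V[idx, idx, drop = FALSE],
    dispersion = disp,
    exposure_spec = attr(crossbasis, "exposure_spec"),
    lag_spec = attr(crossbasis, "lag_spec"),
    window = attr(crossbasis, "window"),
    n_used = sum(keep)
  )
}

#' Package an externally estimated coefficient vector and covariance
#'
#' Builds a `fitted_association` from coefficients and covariance estimated
#' elsewhere (another software package, a published fit, a meta-analysis), so
#' attribution can proceed without refitting. The covariance must be
#' symmetric to within 1e-8 (it is then symmetrized exactly); a zero matrix
#' is accepted and yields degenerate (zero-width) confidence intervals.
#'
#' @param coefficients cross-basis coefficient vector, length
#'   `n_basis(exposure_spec) * n_basis(lag_spec)`, exposure-major order as in
#'   [build_crossbasis()].
#' @param vcov covariance matrix of `coefficients`.
#' @param exposure_spec,lag_spec,window as in [build_crossbasis()];
#'   `exposure_spec` must be centered.
#' @param dispersion optional dispersion to record (not used downstream).
#' @return A `fitted_association`.
#' @export
load_external_fit <- function(coefficients, vcov, exposure_spec, lag_spec,
                              window, dispersion = NA_real_) {
  stopifnot(inherits(exposure_spec, "basis_spec"),
            inherits(lag_spec, "basis_spec"),
            inherits(window, "lag_window"))
  if (is.null(exposure_spec$center_value))
    stop("'exposure_spec' must carry a center_value (the reference x0)")
  p <- n_basis(exposure_spec) * n_basis(lag_spec)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != p)
    stop("expected ", p, " coefficients (", n_basis(exposure_spec), " x ",
         n_basis(lag_spec), "), got ", length(coefficients))
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == p))
    stop("'vcov' must be ", p, " x ", p)
  if (anyNA(coefficients) || anyNA(vcov))
    stop("'coefficients' and 'vcov' must be complete")
  asym <- max(abs(vcov - t(vcov)))
  if (asym > 1e-8 * max(1, max(abs(vcov))))
    stop("'vcov' is not symmetric (max asymmetry ", signif(asym, 3), ")")
  vcov <- (vcov + t(vcov)) / 2
  new_fitted_association(coefficients, vcov, dispersion,
                         exposure_spec, lag_spec, window)
}

#' Export / import cross-basis coefficients and covariance as CSV
#'
#' Writes the coefficient vector and covariance of a `fitted_association`
#' to a labelled CSV at full double precision (17 significant digits), so a
#' fit exported and re-imported reproduces attribution results bit for bit.
#' `import_fit()` rebuilds the `fitted_association` given the basis
#' specifications the coefficients refer to.
#'
#' @param fit a `fitted_association`.
#' @param path CSV file path.
#' @return `export_fit()` returns `path` invisibly; `import_fit()` a
#'   `fitted_association`.
#' @export
export_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fitted_association"))
  p <- length(fit$eta_hat)
  lab <- if (!is.null(names(fit$eta_hat))) names(fit$eta_hat)
         else paste0("eta", seq_len(p))
  m <- cbind(fit$eta_hat, fit$vcov)
  lines <- c(paste(c("term", "coef", lab), collapse = ","),
             vapply(seq_len(p), function(i)
               paste(c(lab[i], sprintf("%.17g", m[i, ])), collapse = ","),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @param exposure_spec,lag_spec,window as in [load_external_fit()].
#' @param dispersion optional dispersion to record.
#' @rdname export_fit
#' @export
import_fit <- function(path, exposure_spec, lag_spec, window,
                       dispersion = NA_real_) {
  raw <- utils::read.csv(path, check.names = FALSE)
  load_external_fit(raw[["coef"]], as.matrix(raw[, -(1:2), drop = FALSE]),
                    exposure_spec, lag_spec, window, dispersion = dispersion)
}
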