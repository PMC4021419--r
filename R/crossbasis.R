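#' Lag window
#'
#' The window of past time steps over which exposure contributes to current
#' risk: `lag_low` (\eqn{\ell_0}) through `lag_high` (\eqn{L}), in units of
#' the series step (days). Lags are 0-based: lag 0 is same-day exposure.
#'
#' @param lag_low,lag_high integers, `0 <= lag_low <= lag_high`.
#' @return An object of class `lag_window`.
#' @export
lag_window <- function(lag_low = 0L, lag_high) {
  lag_low <- as.integer(lag_low); lag_high <- as.integer(lag_high)
  if (is.na(lag_low) || is.na(lag_high) || lag_low < 0L || lag_low > lag_high)
    stop("need 0 <= lag_low <= lag_high")
  structure(list(lag_low = lag_low, lag_high = lag_high),
            class = "lag_window")
}

lags_of <- function(window) window$lag_low:window$lag_high

#' Daily exposure/count series
#'
#' The raw material of all computations: a daily time series of exposure
#' values \eqn{x_t} and (optionally) event counts \eqn{n_t}. Dates must be
#' strictly increasing with a step of one day. Exposure values may be `NA`
#' (they propagate as missing lag histories); counts, where present, must be
#' non-negative integers or `NA`.
#'
#' @param dates `Date` vector, strictly increasing, daily step.
#' @param exposure numeric vector, same length as `dates`.
#' @param counts optional non-negative integer vector, same length.
#' @return A data frame of class `exposure_series` with columns `date`,
#'   `exposure` and (if supplied) `count`.
#' @export
exposure_series <- function(dates, exposure, counts = NULL) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("'dates' contains unparseable or missing entries")
  m <- length(dates)
  if (m < 2L) stop("a series needs at least two days")
  d <- diff(as.integer(dates))
  if (any(d <= 0L)) stop("'dates' must be strictly increasing")
  if (any(d != 1L))
    stop("'dates' must be consecutive days; gap(s) found after ",
         paste(utils::head(dates[which(d != 1L)], 3L), collapse = ", "))
  exposure <- as.numeric(exposure)
  if (length(exposure) != m)
    stop("'exposure' must have the same length as 'dates'")
  out <- data.frame(date = dates, exposure = exposure)
  if (!is.null(counts)) {
    counts <- as.numeric(counts)
    if (length(counts) != m)
      stop("'counts' must have the same length as 'dates'")
    if (any(counts < 0, na.rm = TRUE)) stop("'counts' must be non-negative")
    out$count <- counts
  }
  class(out) <- c("exposure_series", "data.frame")
  out
}

#' Matrix of lagged exposures
#'
#' Arranges the exposure history so that row \eqn{t} holds
#' \eqn{x_{t-\ell_0}, \ldots, x_{t-L}}: column \eqn{j} is the exposure
#' `lag_low + j - 1` steps before \eqn{t}. Entries that would refer to times
#' before the series starts are `NA`; consequently the first `lag_high` rows
#' are incomplete.
#'
#' @param series an [exposure_series()] or a plain numeric exposure vector.
#' @param window a [lag_window()].
#' @return Numeric matrix, rows = series length, columns = lags
#'   `lag_low:lag_high` (named `lag<j>`).
#' @export
build_lag_matrix <- function(series, window) {
  x <- if (inherits(series, "exposure_series")) series$exposure
       else as.numeric(series)
  stopifnot(inherits(window, "lag_window"))
  m <- length(x)
  if (m < window$lag_high + 1L)
    stop("series of length ", m, " has no complete row for lag_high = ",
         window$lag_high)
  lags <- lags_of(window)
  out <- vapply(lags, function(l) {
    if (l == 0L) x else c(rep(NA_real_, l), x[seq_len(m - l)])
  }, numeric(m))
  dimnames(out) <- list(NULL, paste0("lag", lags))
  out
}

#' Cross-basis: tensor-product design columns for a lagged exposure
#'
#' Builds the design matrix whose row \eqn{t} is
#' \deqn{w_{x,t} = \sum_{\ell=\ell_0}^{L} f(x_{t-\ell}) \otimes w(\ell),}
#' the sum over the lag window of the Kronecker product between the centered
#' exposure basis evaluated at the lagged exposure and the lag basis evaluated
#' at the lag itself. A coefficient vector \eqn{\eta} applied to a row then
#' returns the cumulated contribution
#' \eqn{\sum_\ell \beta_{x_{t-\ell},\ell}} of past exposures to the log rate
#' at \eqn{t}, relative to a constant history at the centering value.
#'
#' Columns are ordered exposure-major: column \eqn{(i-1) v_\ell + k} pairs
#' exposure-basis column \eqn{i} with lag-basis column \eqn{k} (names
#' `x<i>.l<k>`). Rows with incomplete lag history (the first `lag_high`
#' observations) and rows whose window contains a missing exposure are `NA`.
#'
#' @param series an [exposure_series()] or numeric exposure vector.
#' @param exposure_spec a centered [basis_spec()] for the exposure dimension
#'   (`center_value` must be set).
#' @param lag_spec a [basis_spec()] for the lag dimension, evaluated at the
#'   integer lags of `window`.
#' @param window a [lag_window()].
#' @return A `crossbasis`: numeric matrix (series length x
#'   `n_basis(exposure_spec) * n_basis(lag_spec)`) with attributes
#'   `exposure_spec`, `lag_spec`, `window` and `df`.
#' @export
build_crossbasis <- function(series, exposure_spec, lag_spec, window) {
  stopifnot(inherits(exposure_spec, "basis_spec"),
            inherits(lag_spec, "basis_spec"),
            inherits(window, "lag_window"))
  if (is.null(exposure_spec$center_value))
    stop("'exposure_spec' must carry a center_value (the reference x0)")
  x <- if (inherits(series, "exposure_series")) series$exposure
       else as.numeric(series)
  m <- length(x)
  if (m < window$lag_high + 1L)
    stop("series of length ", m, " has no complete row for lag_high = ",
         window$lag_high)
  lags <- lags_of(window)
  B <- basis_rows(x, exposure_spec)            # m x vx, centered, NA-tolerant
  W <- basis_rows(lags, lag_spec)              # nl x vl
  vx <- ncol(B); vl <- ncol(W)
  cb <- matrix(0, m, vx * vl)
  for (j in seq_along(lags)) {
    l <- lags[j]
    S <- if (l == 0L) B else
      rbind(matrix(NA_real_, l, vx), B[seq_len(m - l), , drop = FALSE])
    # row-wise kronecker of S (m x vx) with W[j, ] (1 x vl)
    cb <- cb + S[, rep(seq_len(vx), each = vl), drop = FALSE] *
      matrix(rep(W[j, ], vx), m, vx * vl, byrow = TRUE)
  }
  colnames(cb) <- paste0("x", rep(seq_len(vx), each = vl),
                         ".l", rep(seq_len(vl), vx))
  structure(cb, exposure_spec = exposure_spec, lag_spec = lag_spec,
            window = window, df = c(exposure = vx, lag = vl),
            class = c("crossbasis", "matrix", "array"))
}
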