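#' Specify a one-dimensional basis for an exposure or lag dimension
#'
#' A `basis_spec` describes how a single dimension of an exposure-lag-response
#' surface is expanded into spline (or linear) basis columns. The same
#' structure serves the exposure-response function \eqn{f(x)} and the
#' lag-response function \eqn{w(\ell)}; only exposure bases carry a centering
#' value, which fixes the counterfactual reference \eqn{x_0} so that all
#' contrasts are expressed relative to it.
#'
#' @param kind one of `"bspline"`, `"natural_cubic"`, `"linear"`.
#' @param degree polynomial degree for `"bspline"` (ignored otherwise).
#' @param internal_knots strictly increasing knots strictly inside `boundary`.
#'   Ignored (must be empty) for `"linear"`.
#' @param boundary length-2 numeric, the (min, max) of the variable's range;
#'   boundary knots for the spline kinds.
#' @param center_value optional reference value \eqn{x_0}; when set, every
#'   evaluated basis row has the row at `center_value` subtracted, so the
#'   basis (and any linear combination of it) vanishes exactly at \eqn{x_0}.
#' @param intercept logical, keep the full-rank basis including its constant
#'   component. Lag bases conventionally carry an intercept; exposure bases
#'   do not (their constant is absorbed by centering and the model intercept).
#'
#' @return An object of class `basis_spec`.
#' @seealso [evaluate_basis()], [n_basis()], [log_spaced_lag_knots()]
#' @export
#' @examples
#' basis_spec("bspline", degree = 2, internal_knots = c(10, 20),
#'            boundary = c(0, 30), center_value = 15)
basis_spec <- function(kind = c("bspline", "natural_cubic", "linear"),
                       degree = 3L,
                       internal_knots = numeric(0),
                       boundary,
                       center_value = NULL,
                       intercept = FALSE) {
  kind <- match.arg(kind)
  if (missing(boundary) || length(boundary) != 2L || !all(is.finite(boundary)))
    stop("'boundary' must be two finite values (min, max)")
  boundary <- as.numeric(boundary)
  if (boundary[1L] >= boundary[2L])
    stop("'boundary' must satisfy min < max")
  if (kind == "linear") {
    internal_knots <- numeric(0)
    degree <- NA_integer_
  } else {
    degree <- as.integer(degree)
    if (kind == "bspline" && (is.na(degree) || degree < 1L))
      stop("'degree' must be a positive integer for a B-spline basis")
    internal_knots <- as.numeric(internal_knots)
    if (length(internal_knots)) {
      if (any(!is.finite(internal_knots)))
        stop("'internal_knots' must be finite")
      if (is.unsorted(internal_knots, strictly = TRUE))
        stop("'internal_knots' must be strictly increasing")
      if (min(internal_knots) <= boundary[1L] ||
          max(internal_knots) >= boundary[2L])
        stop("'internal_knots' must lie strictly inside the boundary (",
             boundary[1L], ", ", boundary[2L], ")")
    }
  }
  if (!is.null(center_value)) {
    if (length(center_value) != 1L || !is.finite(center_value))
      stop("'center_value' must be a single finite value")
    center_value <- as.numeric(center_value)
    if (center_value < boundary[1L] || center_value > boundary[2L])
      stop("'center_value' must lie within the boundary")
  }
  structure(
    list(kind = kind, degree = degree, internal_knots = internal_knots,
         boundary = boundary, center_value = center_value,
         intercept = isTRUE(intercept)),
    class = "basis_spec"
  )
}

#' Number of basis columns implied by a basis specification
#'
#' @param spec a [basis_spec()].
#' @return Integer number of columns: degree + number of internal knots
#'   (+ 1 with intercept) for B-splines; internal knots + 1 (+ 1 with
#'   intercept) for natural cubic splines; 1 for linear.
#' @export
n_basis <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  nk <- length(spec$internal_knots)
  switch(spec$kind,
    bspline       = spec$degree + nk + as.integer(spec$intercept),
    natural_cubic = nk + 1L + as.integer(spec$intercept),
    linear        = 1L
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec> ", x$kind,
      if (x$kind == "bspline") paste0(" (degree ", x$degree, ")"), "\n",
      "  boundary: [", x$boundary[1L], ", ", x$boundary[2L], "]",
      if (length(x$internal_knots))
        paste0("  knots: ", paste(signif(x$internal_knots, 6), collapse = ", ")),
      "\n",
      "  columns: ", n_basis(x),
      if (!is.null(x$center_value)) paste0("  centered at ", x$center_value),
      if (x$intercept) "  (with intercept)", "\n", sep = "")
  invisible(x)
}

# Basis rows tolerant of NA values (used internally where missing exposures
# must propagate missing rows rather than raise an error).
basis_rows <- function(values, spec) {
  values <- as.numeric(values)
  ok <- is.finite(values)
  out <- matrix(NA_real_, length(values), n_basis(spec))
  if (any(ok)) out[ok, ] <- basis_columns(values[ok], spec)
  if (!is.null(spec$center_value)) {
    ctr <- basis_columns(spec$center_value, spec)
    out <- sweep(out, 2L, as.numeric(ctr), "-")
  }
  out
}

# Uncentered basis evaluation on finite values only.
basis_columns <- function(values, spec) {
  switch(spec$kind,
    bspline = suppressWarnings(splines::bs(
      values, degree = spec$degree, knots = spec$internal_knots,
      Boundary.knots = spec$boundary, intercept = spec$intercept)),
    natural_cubic = splines::ns(
      values, knots = spec$internal_knots,
      Boundary.knots = spec$boundary, intercept = spec$intercept),
    linear = matrix(values, ncol = 1L)
  )
}

#' Evaluate a basis specification at a set of values
#'
#' Expands `values` into the design columns described by `spec`. When the
#' specification carries a `center_value`, the basis row evaluated at that
#' value is subtracted from every row, so the returned matrix is exactly zero
#' at the reference: any coefficient vector applied to it yields a contrast
#' relative to \eqn{x_0}, the re-parameterisation
#' \eqn{\beta_x^* = \beta_x - \beta_{x_0}}.
#'
#' @param values finite numeric vector of evaluation points.
#' @param spec a [basis_spec()].
#' @return A `basis_matrix`: a numeric matrix (length(values) x [n_basis()])
#'   with attributes `values` and `spec`.
#' @details Uncentered B-spline bases with an intercept satisfy the partition
#'   of unity inside the boundary (rows sum to one); natural cubic bases are
#'   linear beyond the boundary knots. Values outside the boundary are
#'   extrapolated by the underlying spline rules.
#' @export
#' @examples
#' sp <- basis_spec("bspline", degree = 2, internal_knots = c(10, 20),
#'                  boundary = c(0, 30), center_value = 15)
#' evaluate_basis(c(0, 15, 30), sp)  # middle row is identically zero
evaluate_basis <- function(values, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' is empty")
  if (any(!is.finite(values)))
    stop("'values' must be finite; found ", sum(!is.finite(values)),
         " non-finite value(s)")
  out <- basis_rows(values, spec)
  dimnames(out) <- list(NULL, paste0("b", seq_len(ncol(out))))
  structure(out, values = values, spec = spec,
            class = c("basis_matrix", "matrix", "array"))
}

#' Lag knots equally spaced on the shifted log scale
#'
#' Places `n_knots` knots for a lag-response basis so that their
#' \eqn{\log(\ell + 1)} values are in arithmetic progression strictly between
#' \eqn{\log(lag_{low} + 1)} and \eqn{\log(lag_{high} + 1)}. The +1 shift
#' makes the transform continuous at lag 0, concentrating knots at short lags
#' where lag-response curves typically change fastest.
#'
#' @param lag_low,lag_high integer lag window bounds, `0 <= lag_low < lag_high`.
#' @param n_knots number of internal knots, at least 1.
#' @return Strictly increasing numeric vector of length `n_knots`, all values
#'   strictly inside `(lag_low, lag_high)`.
#' @export
#' @examples
#' log_spaced_lag_knots(0, 25, 3)
log_spaced_lag_knots <- function(lag_low, lag_high, n_knots) {
  lag_low <- as.integer(lag_low); lag_high <- as.integer(lag_high)
  n_knots <- as.integer(n_knots)
  if (is.na(lag_low) || is.na(lag_high) || lag_low < 0L || lag_low >= lag_high)
    stop("need 0 <= lag_low < lag_high")
  if (is.na(n_knots) || n_knots < 1L) stop("'n_knots' must be >= 1")
  grid <- seq(log(lag_low + 1), log(lag_high + 1), length.out = n_knots + 2L)
  knots <- exp(grid[-c(1L, n_knots + 2L)]) - 1
  if (any(diff(c(lag_low, knots, lag_high)) <= 0))
    stop(n_knots, " knots do not fit strictly inside (", lag_low, ", ",
         lag_high, ")")
  knots
}
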