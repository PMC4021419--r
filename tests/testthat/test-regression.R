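test_that("confounder design has the documented composition", {
  d <- seq(as.Date("2003-01-01"), by = "day", length.out = 365)
  X <- build_confounder_design(d, df_per_year = 10, weekday_indicators = TRUE)
  expect_identical(ncol(X), 1L + 10L + 6L)   # intercept + spline + weekday
  expect_identical(sum(startsWith(colnames(X), "time")), 10L)
  X0 <- build_confounder_design(d, df_per_year = 10,
                                weekday_indicators = FALSE)
  expect_identical(ncol(X0), 11L)
  expect_false(any(startsWith(colnames(X0), "dow")))
  expect_error(build_confounder_design(d, df_per_year = 400), "below")
})

test_that("the seasonal spline tracks a slowly varying annual sinusoid", {
  d <- seq(as.Date("2004-01-01"), by = "day", length.out = 3 * 365)
  X <- build_confounder_design(d, df_per_year = 10,
                               weekday_indicators = FALSE)
  tt <- seq_along(d)
  target <- sin(2 * pi * tt / 365)
  r2 <- summary(lm(target ~ X - 1))$r.squared
  expect_gt(r2, 0.99)
})

test_that("null-effect simulations give coefficients consistent with zero", {
  # no true cross-basis effect: |coef| < 3 SE should hold ~99.7% of the time
  es <- fix_exposure_spec()
  ls <- fix_lag_spec(0L, 5L, 2L)
  w <- lag_window(0L, 5L)
  inside <- 0
  total <- 0
  for (rep in 1:100) {
    set.seed(300 + rep)
    n <- 400
    x <- pmin(pmax(rnorm(n, 15, 5), 0.5), 29.5)
    counts <- rpois(n, 50)
    cb <- build_crossbasis(x, es, ls, w)
    conf <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    fit <- fit_quasipoisson(counts, cb, conf)
    se <- sqrt(diag(fit$vcov))
    inside <- inside + sum(abs(fit$eta_hat) < 3 * se)
    total <- total + length(fit$eta_hat)
  }
  expect_gte(inside / total, 0.95)
})

test_that("Pearson dispersion is near 1 for equidispersed Poisson data", {
  set.seed(31)
  n <- 5000
  x <- pmin(pmax(rnorm(n, 15, 5), 0.5), 29.5)
  counts <- rpois(n, 80)
  cb <- build_crossbasis(x, fix_exposure_spec(), fix_lag_spec(0L, 5L),
                         lag_window(0L, 5L))
  fit <- fit_quasipoisson(counts, cb,
                          matrix(1, n, 1, dimnames = list(NULL, "i")))
  expect_lt(abs(fit$dispersion - 1), 0.1)
})

test_that("the fitted linear predictor reconstructs from its two parts", {
  set.seed(32)
  ser <- fix_series(400, seed = 32)
  es <- fix_exposure_spec()
  ls <- fix_lag_spec(0L, 5L)
  w <- lag_window(0L, 5L)
  cb <- build_crossbasis(ser, es, ls, w)
  conf <- build_confounder_design(ser$date, df_per_year = 4)
  X <- cbind(conf, unclass(cb))
  keep <- complete.cases(X)
  full <- glm.fit(X[keep, ], ser$count[keep], family = quasipoisson())
  fit <- fit_quasipoisson(ser$count, cb, conf)
  eta_lin <- drop(X[keep, ] %*% full$coefficients)
  conf_part <- drop(conf[keep, ] %*%
                      full$coefficients[seq_len(ncol(conf))])
  cb_part <- drop(cb[keep, ] %*% fit$eta_hat)
  expect_lt(max(abs(eta_lin - (conf_part + cb_part))), 1e-8)
})

test_that("a fitted surface is recovered within simulation error", {
  # data generated from a surface the basis can represent; the overall
  # cumulative curve estimate must track the truth closely
  surf <- u_shaped_surface(x0 = 20, scale = 3e-4, decay = 4,
                           window = lag_window(0L, 10L))
  cfg <- simulation_config(n_days = 2000, seed = 33, overdispersion = 1)
  ser <- simulate_series(surf, cfg)
  obs <- range(ser$exposure)
  es <- basis_spec("bspline", degree = 2,
                   internal_knots = seq(obs[1], obs[2], length.out = 4)[2:3],
                   boundary = obs, center_value = 20)
  ls <- basis_spec("natural_cubic",
                   internal_knots = log_spaced_lag_knots(0, 10, 2),
                   boundary = c(0, 10), intercept = TRUE)
  cb <- build_crossbasis(ser, es, ls, lag_window(0L, 10L))
  conf <- build_confounder_design(ser$date, df_per_year = 7)
  fit <- fit_quasipoisson(ser$count, cb, conf)
  xs <- seq(obs[1] + 1, obs[2] - 1, length.out = 9)
  truth <- vapply(xs, function(x)
    sum(vapply(0:10, function(l) surf$g(x, l), numeric(1))), numeric(1))
  est <- overall_cumulative(fit, xs)
  expect_lt(max(abs(est - truth)), 0.12)
})

test_that("external fits round-trip and are validated", {
  es <- fix_exposure_spec()
  ls <- fix_lag_spec(0L, 6L)
  w <- lag_window(0L, 6L)
  p <- n_basis(es) * n_basis(ls)
  set.seed(34)
  eta <- rnorm(p, 0, 0.02)
  A <- matrix(rnorm(p * p), p)
  V <- crossprod(A) / (50 * p)
  fit <- load_external_fit(eta, V, es, ls, w)
  ser <- fix_series(80, seed = 35)
  ref <- backward_attribution(ser, fit)
  # round-trip through the CSV serialization must be bit-identical
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_fit(fit, tmp)
  fit2 <- import_fit(tmp, es, ls, w)
  expect_identical(fit2$eta_hat, unname(fit$eta_hat))
  expect_identical(backward_attribution(ser, fit2)$af, ref$af)

  Vbad <- V; Vbad[1, 2] <- Vbad[1, 2] + 1e-3
  expect_error(load_external_fit(eta, Vbad, es, ls, w), "symmetric")
  expect_error(load_external_fit(eta[-1], V, es, ls, w), "coefficients")
  # zero covariance is legal (degenerate-interval use)
  expect_s3_class(load_external_fit(eta, matrix(0, p, p), es, ls, w),
                  "fitted_association")
})

test_that("rank-deficient designs are rejected with the offending columns", {
  ser <- fix_series(100, seed = 36)
  cb <- build_crossbasis(ser, fix_exposure_spec(), fix_lag_spec(0L, 5L),
                         lag_window(0L, 5L))
  conf <- cbind(a = rep(1, 100), b = rep(2, 100))  # collinear pair
  expect_error(fit_quasipoisson(ser$count, cb, conf), "collinear")
})
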