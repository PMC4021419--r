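test_that("the attributable-fraction transform satisfies its identities", {
  expect_identical(attributable_fraction(0), 0)
  expect_equal(attributable_fraction(log(2)), 0.5)       # AF = (RR-1)/RR at RR=2
  expect_equal(attributable_fraction(-0.1), 1 - exp(0.1))
  expect_error(attributable_fraction(Inf), "finite")
  # joint combination
  expect_equal(joint_attributable_fraction(c(log(2), log(2))), 0.75)
  expect_identical(joint_attributable_fraction(numeric(0)), 0)
  # joint <= sum of individual AFs for non-negative contributions
  set.seed(50)
  for (i in 1:1000) {
    betas <- rexp(sample(1:6, 1), rate = 5)
    expect_lte(joint_attributable_fraction(betas),
               sum(attributable_fraction(betas)) + 1e-12)
  }
})

test_that("backward attribution matches the brute-force double loop", {
  fit <- fix_fit(seed = 51, sd = 0.05, lag_high = 6L,
                 lag_spec = fix_lag_spec(0L, 6L))
  ser <- fix_series(50, seed = 52)
  for (r in list(NULL, exposure_range(-Inf, 15, closure = "()"),
                 exposure_range(12, 22, closure = "[)"))) {
    got <- backward_attribution(ser, fit, r)
    want <- brute_backward_af(ser$exposure, fit$eta_hat, fit$exposure_spec,
                              fit$lag_spec, fit$window, r)
    expect_identical(is.na(got$af), is.na(want))
    ok <- !is.na(want)
    expect_lt(max(abs(got$af[ok] - want[ok])), 1e-10)
    expect_equal(got$an[ok], got$af[ok] * ser$count[ok], tolerance = 1e-12)
  }
})

test_that("zero coefficients attribute nothing; constant series give the closed form", {
  es <- fix_exposure_spec()
  ls <- fix_lag_spec(0L, 10L)
  w <- lag_window(0L, 10L)
  p <- n_basis(es) * n_basis(ls)
  null_fit <- load_external_fit(rep(0, p), matrix(0, p, p), es, ls, w)
  ser <- fix_series(40, seed = 53)
  ba <- backward_attribution(ser, null_fit)
  expect_true(all(ba$af[!is.na(ba$af)] == 0) && all(ba$an[!is.na(ba$an)] == 0))
  # constant series at x with cumulative contribution ln 2 and n = 100:
  # af = 0.5, an = 50 on every complete day
  fit <- fix_fit(seed = 54, sd = 0.05)
  xstar <- 25
  scale <- log(2) / overall_cumulative(fit, xstar)
  fit2 <- load_external_fit(fit$eta_hat * scale, fit$vcov, fit$exposure_spec,
                            fit$lag_spec, fit$window)
  d <- seq(as.Date("2002-01-01"), by = "day", length.out = 40)
  cser <- exposure_series(d, rep(xstar, 40), counts = rep(100, 40))
  ba2 <- backward_attribution(cser, fit2)
  complete <- !is.na(ba2$af)
  expect_equal(ba2$af[complete], rep(0.5, sum(complete)), tolerance = 1e-10)
  expect_equal(ba2$an[complete], rep(50, sum(complete)), tolerance = 1e-8)
  # and backward equals forward on a constant series (interior days)
  fa2 <- forward_attribution(cser, fit2, tail = "missing")
  both <- !is.na(ba2$af) & !is.na(fa2$an)
  expect_equal(ba2$af[both], fa2$af[both], tolerance = 1e-12)
})

test_that("forward attribution averages future counts and matches its oracle", {
  fit <- fix_fit(seed = 55, sd = 0.05, lag_high = 2L,
                 lag_spec = fix_lag_spec(0L, 2L))
  d <- seq(as.Date("2002-01-01"), by = "day", length.out = 3)
  ser <- exposure_series(d, c(25, 10, 18), counts = c(10, 20, 30))
  fa <- forward_attribution(ser, fit)
  af1 <- 1 - exp(-overall_cumulative(fit, 25))
  expect_equal(fa$an[1], af1 * 20, tolerance = 1e-12)  # mean(10, 20, 30)
  # tail truncation reduces the divisor; "missing" marks the tail NA
  expect_equal(fa$an[2], fa$af[2] * 25, tolerance = 1e-12)
  fam <- forward_attribution(ser, fit, tail = "missing")
  expect_true(is.na(fam$an[2]) && is.na(fam$an[3]) && !is.na(fam$an[1]))
  # constant counts: an = af * nbar
  ser2 <- fix_series(60, seed = 56)
  ser2$count <- rep(80, 60)
  fa2 <- forward_attribution(ser2, fit)
  expect_equal(fa2$an, fa2$af * 80, tolerance = 1e-12)
  # oracle agreement on the fractions
  want <- brute_forward_af(ser2$exposure, fit$eta_hat, fit$exposure_spec,
                           fit$lag_spec, fit$window)
  expect_lt(max(abs(fa2$af - want)), 1e-10)
})

test_that("a reduced overall-cumulative curve supports forward attribution", {
  fit <- fix_fit(seed = 57, sd = 0.05)
  ser <- fix_series(50, seed = 58)
  full <- forward_attribution(ser, fit)
  curve <- function(x) overall_cumulative(fit, x)
  reduced <- forward_attribution(ser, curve, window = fit$window)
  expect_equal(reduced$af, full$af, tolerance = 1e-12)
  expect_equal(reduced$an, full$an, tolerance = 1e-12)
  expect_error(forward_attribution(ser, curve), "window")
})

test_that("forward components are exactly additive, backward sub-additive", {
  fit <- fix_fit(seed = 59, sd = 0.08)
  ser <- fix_series(120, seed = 60)
  x0 <- fit$center_value
  r1 <- exposure_range(-Inf, 10, closure = "(]")
  r2 <- exposure_range(10, Inf, closure = "()")
  f_all <- forward_attribution(ser, fit)
  f1 <- forward_attribution(ser, fit, r1)
  f2 <- forward_attribution(ser, fit, r2)
  expect_identical(f1$af + f2$af, f_all$af)   # exact additivity
  # backward: sub-additivity where the selected contributions are >= 0,
  # via a linear exposure basis with a positive lag profile (so every
  # contribution at non-negative exposure is non-negative)
  esl <- basis_spec("linear", boundary = c(0, 30), center_value = 0)
  lsl <- fix_lag_spec(0L, 6L)
  pl <- n_basis(esl) * n_basis(lsl)
  wl <- evaluate_basis(0:6, lsl)
  # choose eta so the lag profile is positive at every lag
  eta_lin <- qr.coef(qr(unclass(wl)), rep(0.01, 7))
  fitpos <- load_external_fit(eta_lin, matrix(0, pl, pl), esl, lsl,
                              lag_window(0L, 6L))
  b_all <- backward_attribution(ser, fitpos)
  b1 <- backward_attribution(ser, fitpos, exposure_range(-Inf, 15,
                                                         closure = "()"))
  b2 <- backward_attribution(ser, fitpos, exposure_range(15, Inf,
                                                         closure = "[)"))
  ok <- !is.na(b_all$af)
  expect_true(all(b_all$af[ok] <= b1$af[ok] + b2$af[ok] + 1e-12))
  # and every fraction stays below 1
  expect_true(all(b_all$af[ok] < 1))
})

test_that("totals follow the summation definitions, negatives included", {
  d <- seq(as.Date("2002-01-01"), by = "day", length.out = 2)
  ser <- exposure_series(d, c(10, 20), counts = c(100, 100))
  daily <- structure(
    data.frame(date = ser$date, exposure = ser$exposure, count = ser$count,
               af = c(0.05, -0.02), an = c(5, -2)),
    perspective = "backward", range = NULL, range_label = "overall",
    class = c("attribution_series", "data.frame"))
  tot <- total_attribution(daily)
  expect_equal(tot$an_total, 3)
  expect_equal(tot$af_total, 0.015)
  # zeros give zero totals
  daily0 <- daily; daily0$af <- daily0$an <- c(0, 0)
  tot0 <- total_attribution(daily0)
  expect_identical(c(tot0$an_total, tot0$af_total), c(0, 0))
  # forward component totals add up to the overall forward total
  fit <- fix_fit(seed = 62, sd = 0.06)
  ser2 <- fix_series(150, seed = 63)
  r1 <- exposure_range(-Inf, 15, closure = "()")
  r2 <- exposure_range(15, Inf, closure = "[)")
  t_all <- total_attribution(forward_attribution(ser2, fit))
  t1 <- total_attribution(forward_attribution(ser2, fit, r1))
  t2 <- total_attribution(forward_attribution(ser2, fit, r2))
  expect_equal(t1$an_total + t2$an_total, t_all$an_total, tolerance = 1e-10)
  expect_equal(t1$af_total + t2$af_total, t_all$af_total, tolerance = 1e-10)
})

test_that("Monte Carlo intervals are deterministic and degenerate at zero vcov", {
  ser <- fix_series(100, seed = 64)
  fit0 <- fix_fit(seed = 65, sd = 0.05)          # zero covariance
  s0 <- montecarlo_eci(ser, fit0, perspective = "backward", n_sim = 50,
                       seed = 9)
  expect_identical(unname(s0$eci_af), rep(unname(s0$af_total), 2))
  expect_identical(unname(s0$eci_an), rep(unname(s0$an_total), 2))
  fit <- fix_fit(seed = 65, sd = 0.05, vcov_scale = 1e-4)
  a <- montecarlo_eci(ser, fit, perspective = "backward", n_sim = 200,
                      seed = 10)
  b <- montecarlo_eci(ser, fit, perspective = "backward", n_sim = 200,
                      seed = 10)
  expect_identical(a$eci_af, b$eci_af)
  expect_identical(a$eci_an, b$eci_an)
  expect_lt(a$eci_af[1], a$eci_af[2])
  # the point estimate agrees with the daily-series route
  tot <- total_attribution(backward_attribution(ser, fit))
  expect_equal(unname(a$an_total), tot$an_total, tolerance = 1e-10)
  # forward perspective runs through the same machinery
  f <- montecarlo_eci(ser, fit, perspective = "forward", n_sim = 100,
                      seed = 11)
  totf <- total_attribution(forward_attribution(ser, fit))
  expect_equal(unname(f$an_total), totf$an_total, tolerance = 1e-10)
  # validation: a broken covariance is refused
  fit_bad <- fit
  fit_bad$vcov <- -diag(length(fit$eta_hat))
  expect_error(montecarlo_eci(ser, fit_bad, perspective = "backward",
                              n_sim = 10, seed = 1), "semi-definite")
})

test_that("range machinery classifies endpoints by closure", {
  r <- exposure_range(0, 10, closure = "(]")
  expect_identical(in_range(c(0, 5, 10, 11), r), c(FALSE, TRUE, TRUE, FALSE))
  r2 <- exposure_range(0, 10, closure = "[)")
  expect_identical(in_range(c(0, 10), r2), c(TRUE, FALSE))
  expect_error(exposure_range(5, 5), "strictly below")
  rs <- standard_ranges(c(rnorm(500, 15, 5)), x0 = 20)
  expect_named(rs, c("cold", "heat", "extreme_cold", "mild_cold",
                     "mild_heat", "extreme_heat"))
  expect_lt(rs$extreme_cold$high, 20)
  expect_gt(rs$extreme_heat$low, 20)
})
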