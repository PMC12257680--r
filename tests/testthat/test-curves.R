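test_that("quantile knots sit at group quantiles with boundaries and dedup", {
  pos <- seq(0, 100, length.out = 1001)
  kn <- quantile_knots(pos, 10)
  expect_equal(kn, seq(0, 100, by = 10), tolerance = 1e-6)

  # extra knot overlapping a quantile knot is kept once
  kn2 <- quantile_knots(pos, 10, extra_knots = c(20, 33))
  expect_equal(sum(abs(kn2 - 20) < 1e-9), 1L)
  expect_true(33 %in% kn2)

  expect_error(quantile_knots(c(1, 2), 10), "distinct positions")
})

test_that("penalized spline solves the exact normal equations", {
  set.seed(4)
  x <- sort(runif(40, 0, 100))
  y <- sin(x / 15) + rnorm(40, 0, 0.2)
  kn <- quantile_knots(x, 10)
  cfg <- smoothing_config(order = 4, lambda_smooth = 2500, prediction_step = 1)
  fit <- fit_penalized_spline(x, y, kn, cfg)

  aug <- c(rep(kn[1], 3), kn, rep(kn[length(kn)], 3))
  B <- splines::splineDesign(aug, x, ord = 4)
  R <- penalty_gram(kn, 4)
  oracle <- solve(crossprod(B) + 2500 * R, crossprod(B, y))
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-10)
})

test_that("penalty null space: linear data reproduced exactly at any lambda", {
  x <- seq(0, 60, by = 3)
  y <- 2 + 0.5 * x
  kn <- quantile_knots(x, 8)
  for (lam in c(0.01, 2500, 1e8)) {
    fit <- fit_penalized_spline(x, y, kn, smoothing_config(order = 4, lambda_smooth = lam))
    expect_lt(max(abs(evaluate_curve(fit, x) - y)), 1e-7)
  }
})

test_that("lambda to infinity approaches the least-squares straight line", {
  set.seed(9)
  x <- seq(0, 100, length.out = 30)
  y <- 1 + 0.3 * x + rnorm(30, 0, 0.5)
  kn <- quantile_knots(x, 10)
  fit <- fit_penalized_spline(x, y, kn, smoothing_config(order = 4, lambda_smooth = 1e9))
  ols <- lm(y ~ x)
  expect_lt(max(abs(evaluate_curve(fit, x) - fitted(ols))), 1e-3)
})

test_that("lambda zero with square basis interpolates the data", {
  set.seed(2)
  kn <- c(0, 25, 50, 75, 100)   # 4 + order - 2 = 7 basis functions for order 4
  x <- c(0, 10, 30, 45, 60, 80, 100)
  y <- rnorm(7)
  fit <- fit_penalized_spline(x, y, kn, smoothing_config(order = 4, lambda_smooth = 0))
  expect_lt(max(abs(evaluate_curve(fit, x) - y)), 1e-6)
})

test_that("RSS is non-increasing as lambda decreases on fixed data and knots", {
  set.seed(5)
  x <- sort(runif(35, 0, 80))
  y <- cos(x / 10) + rnorm(35, 0, 0.3)
  kn <- quantile_knots(x, 10)
  rss <- vapply(c(1e6, 1e4, 1e2, 1, 0), function(lam) {
    fit <- fit_penalized_spline(x, y, kn, smoothing_config(order = 4, lambda_smooth = lam))
    sum((evaluate_curve(fit, x) - y)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("fit is invariant to permutation of the input records", {
  set.seed(6)
  x <- sort(runif(25, 0, 50))
  y <- x * 0.1 + rnorm(25, 0, 0.1)
  kn <- quantile_knots(x, 8)
  cfg <- smoothing_config(order = 3, lambda_smooth = 10)
  perm <- sample.int(25)
  f1 <- fit_penalized_spline(x, y, kn, cfg)
  f2 <- fit_penalized_spline(x[perm], y[perm], kn, cfg)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
})

test_that("derivative evaluation agrees with central differences", {
  set.seed(8)
  x <- sort(runif(30, 0, 40))
  y <- rnorm(30)
  kn <- quantile_knots(x, 6)
  fit <- fit_penalized_spline(x, y, kn, smoothing_config(order = 4, lambda_smooth = 1))
  g <- seq(1, 39, by = 0.5)
  h <- 1e-4
  num <- (evaluate_curve(fit, g + h) - evaluate_curve(fit, g - h)) / (2 * h)
  expect_lt(max(abs(evaluate_curve(fit, g, deriv = 1) - num)), 1e-5)
})

test_that("fit errors cleanly on bad inputs", {
  x <- seq(0, 10, length.out = 8)
  kn <- c(0, 5, 10)
  expect_error(fit_penalized_spline(x[1:3], rnorm(3), kn, smoothing_config(order = 4)),
               "order \\+ 1")
  expect_error(fit_penalized_spline(c(x, 12), rnorm(9), kn, smoothing_config(order = 4)),
               "outside")
  expect_error(evaluate_curve(
    fit_penalized_spline(x, rnorm(8), kn, smoothing_config(order = 4, lambda_smooth = 1)),
    c(5, 11)), "outside")
})

test_that("standardization is exact per cell, idempotent, and errors on constants", {
  rec <- data.frame(animal = c(1, 2, 3), series = "FD",
                    position = c(0, 0, 0), value = c(10, 12, 14),
                    flock_year = "A")
  out <- standardize_raw(rec)
  expect_equal(out$value, c(-1, 0, 1))
  # idempotence
  out2 <- standardize_raw(out)
  expect_equal(out2$value, out$value, tolerance = 1e-12)
  rec$value <- c(3, 3, 3)
  expect_error(standardize_raw(rec), "zero within-group")
})

test_that("body-weight standardization cells split by recording moment", {
  set.seed(10)
  # two occasions (days ~90 and ~150) in one flock-year
  rec <- data.frame(animal = rep(1:6, times = 2), series = "BW",
                    position = c(rnorm(6, 90, 1), rnorm(6, 150, 1)),
                    value = c(rnorm(6, 20, 2), rnorm(6, 30, 3)),
                    flock_year = "A")
  out <- standardize_raw(rec)
  expect_equal(length(unique(out$std_cell)), 2L)
  for (cl in unique(out$std_cell)) {
    v <- out$value[out$std_cell == cl]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})
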