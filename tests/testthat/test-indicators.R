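test_that("deviation indicators match their closed forms", {
  expect_equal(lnvar(c(0.5, -0.5, 0.5, -0.5)), log(1 / 3))
  expect_equal(auto_lag1(c(1, -1, 1, -1)), -0.75)
  expect_equal(auto_lag1(c(1, 1, -1, -1)), 0.25)
  expect_equal(dev_skewness(c(-1, 0, 1)), 0)
  expect_equal(dev_skewness(c(0, 0, 3)), (2 / sqrt(3))^3 / 3 - 2 * (1 / sqrt(3))^3 / 3)
  expect_equal(abs_change(c(0, 1, 3, 2)), 4 / 3)
  expect_equal(abs_change(rep(2, 5)), 0)
})

test_that("indicator invariances hold", {
  set.seed(13)
  x <- rnorm(50)
  # scaling: Lnvar shifts by 2 log|c|, ABS is homogeneous, skewness invariant
  expect_equal(lnvar(3 * x), lnvar(x) + 2 * log(3), tolerance = 1e-12)
  expect_equal(abs_change(-2 * x), 2 * abs_change(x), tolerance = 1e-12)
  expect_equal(dev_skewness(x + 5), dev_skewness(x), tolerance = 1e-9)
  # grid reversal
  xr <- rev(x)
  expect_equal(lnvar(xr), lnvar(x))
  expect_equal(dev_skewness(xr), dev_skewness(x))
  expect_equal(auto_lag1(xr), auto_lag1(x))
  expect_equal(abs_change(xr), abs_change(x))
  # degenerate inputs flagged missing, not infinite
  expect_true(is.na(lnvar(rep(1, 4))))
  expect_true(is.na(auto_lag1(rep(2, 5))))
  expect_true(is.na(dev_skewness(rep(0, 5))))
})

test_that("indicators match brute-force loop implementations on random series", {
  brute_lnvar <- function(x) {
    m <- mean(x); ss <- 0
    for (xi in x) ss <- ss + (xi - m)^2
    log(ss / (length(x) - 1))
  }
  brute_auto <- function(x) {
    m <- mean(x); num <- 0; den <- 0
    for (i in seq_len(length(x) - 1)) num <- num + (x[i] - m) * (x[i + 1] - m)
    for (i in seq_along(x)) den <- den + (x[i] - m)^2
    num / den
  }
  brute_skew <- function(x) {
    m <- mean(x); ss <- 0
    for (xi in x) ss <- ss + (xi - m)^2
    s <- sqrt(ss / (length(x) - 1)); acc <- 0
    for (xi in x) acc <- acc + ((xi - m) / s)^3
    acc / length(x)
  }
  brute_abs <- function(x) {
    acc <- 0
    for (i in 2:length(x)) acc <- acc + abs(x[i] - x[i - 1])
    acc / (length(x) - 1)
  }
  set.seed(99)
  for (rep in 1:200) {
    x <- rnorm(sample(5:60, 1))
    expect_lt(abs(lnvar(x) - brute_lnvar(x)), 1e-12)
    expect_lt(abs(auto_lag1(x) - brute_auto(x)), 1e-12)
    expect_lt(abs(dev_skewness(x) - brute_skew(x)), 1e-12)
    expect_lt(abs(abs_change(x) - brute_abs(x)), 1e-12)
  }
})

test_that("lag-1 autocorrelation recovers AR(1) persistence at large n", {
  set.seed(14)
  n <- 10000
  x <- as.numeric(arima.sim(list(ar = 0.8), n))
  expect_lt(abs(auto_lag1(x) - 0.8), 0.03)
})

test_that("deviations are pointwise differences and average to zero about the mean", {
  set.seed(15)
  grid <- seq(0, 50, by = 1)
  curves <- sapply(1:8, function(j) sin(grid / 10) + rnorm(length(grid), 0, 0.1))
  mc <- rowMeans(curves)
  dev <- compute_deviations(curves, mc, grid)
  expect_equal(dev[, 3], curves[, 3] - mc)
  expect_lt(max(abs(rowSums(dev))), 1e-10)
  # constant offset propagates exactly
  dev2 <- compute_deviations(curves[, 1, drop = FALSE] + 0.3, curves[, 1], grid)
  expect_equal(unname(dev2[, 1]), rep(0.3, length(grid)))
  expect_error(compute_deviations(curves, mc[-1], grid), "mismatch")
})

test_that("weaning window detection finds constructed extrema and rejects monotone means", {
  g <- seq(0, 100, by = 0.5)
  dip <- function(t, c0, d, w) -d * exp(-0.5 * ((t - c0) / w)^2)
  mc <- 0.002 * g + dip(g, 45, 1, 6)
  w <- detect_weaning_window(mc, g, anchor = 30, prominence = 0.2)
  expect_true(w$detected)
  expect_lt(abs(w$t_min - 45), 1)
  expect_gt(w$t_max, w$t_min)
  expect_false(detect_weaning_window(0.01 * g, g, anchor = 30)$detected)
  expect_error(detect_weaning_window(mc, g, anchor = 200), "anchor")
})

test_that("prominence threshold skips shallow first dips", {
  g <- seq(0, 100, by = 0.5)
  mc <- -0.05 * exp(-0.5 * ((g - 40) / 3)^2) - 1 * exp(-0.5 * ((g - 65) / 5)^2)
  w <- detect_weaning_window(mc, g, anchor = 30, prominence = 0.3,
                             search_span = 60)
  expect_true(w$detected)
  expect_lt(abs(w$t_min - 65), 1.5)
})

test_that("age maps proportionally onto the staple", {
  expect_equal(map_age_to_staple(90, 300, 60), 18)
  expect_equal(map_age_to_staple(0, 300, 60), 0)
  expect_equal(map_age_to_staple(300, 300, 60), 60)
  expect_error(map_age_to_staple(301, 300, 60), "age outside")
})

test_that("ROC and ABC arithmetic on the group window", {
  grid <- seq(80, 150, by = 1)
  win <- structure(list(t_w = 90, t_min = 110, t_max = 135, detected = TRUE),
                   class = "weaning_window")
  f <- approx(c(80, 90, 110, 135, 150), c(0, 0, -0.4, 0.1, 0.1), xout = grid)$y
  roc <- roc_traits(f, grid, win)
  expect_equal(unname(roc["ROC_response"]), -0.02, tolerance = 1e-10)
  expect_equal(unname(roc["ROC_recovery"]), 0.02, tolerance = 1e-10)
  flat <- rep(0.2, length(grid))
  expect_equal(unname(roc_traits(flat, grid, win)), c(0, 0))

  mc <- sin(grid / 20)
  expect_equal(abc_trait(mc, mc, grid, win), 0)
  span <- win$t_max - win$t_w
  expect_equal(abc_trait(mc + 0.2, mc, grid, win), 0.2 * span, tolerance = 1e-9)
  expect_equal(abc_trait(mc - 0.2, mc, grid, win), -0.2 * span, tolerance = 1e-9)

  undet <- structure(list(detected = FALSE), class = "weaning_window")
  expect_true(all(is.na(roc_traits(f, grid, undet))))
  expect_true(is.na(abc_trait(f, mc, grid, undet)))
})

test_that("3-SD outlier rule masks exactly the planted outlier, single pass", {
  set.seed(16)
  vals <- c(rnorm(100), 10)
  tab <- data.frame(animal = seq_along(vals), flock_year = "A",
                    trait = "Lnvar", value = vals)
  out <- remove_outliers(tab)
  expect_equal(nrow(out$log), 1L)
  expect_equal(out$log$animal, 101L)
  expect_true(is.na(out$traits$value[101]))
  expect_equal(sum(out$traits$outlier_flag), 1L)
  # all-equal group: nothing removed
  tab2 <- data.frame(animal = 1:5, flock_year = "B", trait = "ABS", value = 1)
  expect_equal(nrow(remove_outliers(tab2)$log), 0L)
})
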