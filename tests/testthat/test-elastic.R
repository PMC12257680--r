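test_that("SRVF transform matches analytic forms", {
  t <- unit_grid(201)
  expect_equal(srvf_transform(t, t)$q, rep(1, 201), tolerance = 1e-12)
  expect_equal(srvf_transform(1 - t, t)$q, rep(-1, 201), tolerance = 1e-12)
  # f = t^2 -> q = sqrt(2t); centered differences are O(h^2) except the ends
  q <- srvf_transform(t^2, t)
  inner <- 2:200
  expect_lt(max(abs(q$q[inner] - sqrt(2 * t[inner]))), 0.05)
  expect_error(srvf_transform(c(1, 2), c(0, 1)), "3 points")
})

test_that("optimal warp is identity for matched curves and under heavy penalty", {
  t <- unit_grid()
  f <- sin(2 * pi * t) + 2 * t
  q <- srvf_transform(f, t)
  w <- optimal_warp(q, q, 0)
  expect_lt(max(abs(w$gamma - t)), diff(t[1:2]) + 1e-12)

  f2 <- approx(t, f, xout = t^1.3)$y
  q2 <- srvf_transform(f2, t)
  wbig <- optimal_warp(q2, q, 1e6)
  expect_lt(max(abs(wbig$gamma - t)), 1e-10)
})

test_that("warping a known deformation recovers most of the elastic distance", {
  t <- unit_grid()
  f <- sin(2 * pi * t) + 2 * t
  mu <- srvf_transform(f, t)
  set.seed(31)
  for (expo in c(0.75, 1.35)) {
    fw <- approx(t, f, xout = t^expo)$y
    qw <- srvf_transform(fw, t)
    w <- optimal_warp(qw, mu, 0)
    d_before <- woolres:::srvf_distance(qw, mu)
    d_after <- woolres:::srvf_distance(woolres:::warp_srvf(qw, w), mu)
    expect_lt(d_after, 0.1 * d_before)
  }
})

test_that("warp invariants are enforced on all outputs", {
  t <- unit_grid(51)
  set.seed(32)
  f <- cumsum(rnorm(51))
  q <- srvf_transform(f, t)
  mu <- srvf_transform(sin(2 * pi * t), t)
  for (lam in c(0, 0.2, 0.6)) {
    w <- optimal_warp(q, mu, lam)
    expect_equal(w$gamma[1], 0)
    expect_equal(w$gamma[51], 1)
    expect_true(all(diff(w$gamma) >= -1e-12))
  }
  expect_error(woolres:::new_warp_function(t, rev(t)), "endpoints|non-decreasing")
})

test_that("sup warp deviation is non-increasing in the alignment penalty", {
  t <- unit_grid()
  f <- sin(2 * pi * t) + 2 * t
  mu <- srvf_transform(f, t)
  set.seed(33)
  for (rep in 1:4) {
    expo <- runif(1, 0.7, 1.4)
    q <- srvf_transform(approx(t, f, xout = t^expo)$y, t)
    sup <- vapply(c(0, 0.2, 0.4, 0.6), function(l) {
      max(abs(optimal_warp(q, mu, l)$gamma - t))
    }, numeric(1))
    expect_true(all(diff(sup) <= 1e-9))
  }
})

test_that("apply_warp composes curves and respects monotonicity", {
  t <- unit_grid()
  f <- exp(t)
  id <- woolres:::new_warp_function(t, t)
  expect_equal(apply_warp(f, t, id), f)
  g0 <- t^1.5
  w <- woolres:::new_warp_function(t, g0)
  fw <- apply_warp(f, t, w)
  expect_true(all(diff(fw) > 0))     # monotone in, monotone out
  # gamma then gamma-inverse restores the curve
  winv <- woolres:::invert_warp(w)
  back <- apply_warp(fw, t, winv)
  expect_lt(max(abs(back - f)), 1e-3)
})

test_that("Karcher mean: identical members converge immediately and are permutation stable", {
  t <- unit_grid(81)
  f <- sin(2 * pi * t)
  q <- srvf_transform(f, t)
  qs <- list(q, q, q)
  km <- karcher_mean(qs, 0)
  expect_equal(km$mean$q, q$q, tolerance = 1e-10)
  expect_true(km$converged)

  set.seed(34)
  qs2 <- lapply(c(0.8, 1.25), function(e) srvf_transform(approx(t, f, xout = t^e)$y, t))
  m1 <- karcher_mean(qs2, 0.2)
  m2 <- karcher_mean(rev(qs2), 0.2)
  expect_equal(m1$mean$q, m2$mean$q, tolerance = 1e-10)
})

test_that("Karcher objective is monotone and warped copies rebuild the template", {
  t <- unit_grid()
  f <- sin(2 * pi * t) + 2 * t
  set.seed(35)
  # balanced phase population: every warp paired with its inverse, so phase
  # variation has no net drift (as with any centered phase process)
  es <- runif(12, 1.05, 1.35)
  curves <- sapply(c(es, 1 / es), function(e) approx(t, f, xout = t^e)$y)
  ga <- align_group(curves, t, lambda_grid = 0, tol = 1e-6, max_iter = 50)
  entry <- ga[["lambda_0"]]
  # monotone up to the discretization slack between the DP path integral and
  # the trapezoid distance used for reporting
  obj <- entry$objective
  expect_true(all(diff(obj) <= 1e-4 * pmax(1, head(obj, -1))))
  rel_err <- sqrt(woolres:::trapz(t, (entry$mean_curve - f)^2)) /
    sqrt(woolres:::trapz(t, f^2))
  expect_lt(rel_err, 0.05)
  # phase-only variation: cross-sectional variance drops by >= 80%
  v_pre <- mean(apply(curves, 1, var))
  v_post <- mean(apply(entry$aligned, 1, var))
  expect_lt(v_post, 0.2 * v_pre)
  # alignment distance never worse than unaligned distance to the mean
  qs <- lapply(seq_len(ncol(curves)), function(j) srvf_transform(curves[, j], t))
  d_un <- vapply(qs, function(q) woolres:::srvf_distance(q, entry$mean_srvf), numeric(1))
  expect_true(all(entry$distances <= d_un + 1e-8))
})

test_that("align_group emits one complete alignment per requested lambda", {
  t <- unit_grid(61)
  set.seed(36)
  curves <- sapply(1:6, function(i) sin(2 * pi * t) + rnorm(61, 0, 0.05))
  ga <- align_group(curves, t, lambda_grid = c(0, 0.2, 0.4, 0.6))
  expect_named(ga, c("lambda_0", "lambda_0.2", "lambda_0.4", "lambda_0.6"))
  for (entry in ga) {
    expect_equal(dim(entry$aligned), dim(curves))
    expect_length(entry$warps, 6L)
  }
  expect_error(align_group(curves[, 1, drop = FALSE], t), "too small")
  expect_error(align_group(curves, t, lambda_grid = numeric(0)), "non-empty")
})

test_that("a group of identical curves aligns to itself with identity warps", {
  t <- unit_grid(61)
  f <- cos(2 * pi * t)
  curves <- matrix(rep(f, 5), ncol = 5)
  ga <- align_group(curves, t, lambda_grid = 0.2)
  entry <- ga[["lambda_0.2"]]
  expect_equal(entry$mean_curve, f, tolerance = 1e-8)
  for (w in entry$warps) expect_lt(max(abs(w$gamma - t)), 1e-8)
})
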