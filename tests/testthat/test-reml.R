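test_that("model frame builds full-rank designs and singleton maternal levels", {
  ped <- nested_pedigree(2, 2, 2)
  lambs <- ped$animal[ped$generation == 1]
  dat <- data.frame(animal = lambs, value = rnorm(8),
                    flock_year = rep(c("A", "B"), 4), sex = "F",
                    brt = rep(c("11", "22"), each = 4))
  fr <- model_frame(dat, ped)
  expect_equal(fr$n, 8L)
  expect_equal(qr(fr$X)$rank, ncol(fr$X))
  expect_equal(fr$s, 4L)   # 4 distinct dams

  # unknown dams become singleton levels
  ped2 <- half_sib_pedigree(2, 3)
  dat2 <- data.frame(animal = ped2$animal[-(1:2)], value = rnorm(6))
  fr2 <- model_frame(dat2, ped2, fixed = character(0))
  expect_equal(fr2$s, 6L)

  expect_error(model_frame(data.frame(animal = 999, value = 1), ped),
               "pedigree")
})

test_that("REML equals the ANOVA estimators on a balanced half-sib design", {
  set.seed(51)
  s <- 30; n <- 15
  ped <- half_sib_pedigree(s, n)
  dat <- half_sib_phenotypes(ped, s, n, sigma2_a = 0.4, sigma2_e = 0.6)
  fr <- model_frame(dat, ped, fixed = character(0), maternal = FALSE)
  fit <- reml_univariate(fr, blend_and_build_H(ped))

  y <- matrix(dat$value, n, s)
  msb <- n * var(colMeans(y))
  msw <- mean(apply(y, 2, var))
  sire_var <- (msb - msw) / n
  expect_lt(abs(fit$varcomp["sigma2_a"] - 4 * sire_var), 1e-6)
  expect_lt(abs(fit$varcomp["sigma2_e"] - (msw - 3 * sire_var)), 1e-6)
  expect_true(all(diff(fit$trajectory) <= 1e-6))
})

test_that("pure-noise phenotypes on a family structure drive sigma2_a to zero", {
  set.seed(52)
  ped <- half_sib_pedigree(25, 10)
  dat <- data.frame(animal = ped$animal[-(1:25)], value = rnorm(250))
  fit <- reml_univariate(model_frame(dat, ped, fixed = character(0), maternal = FALSE),
                         blend_and_build_H(ped))
  expect_lt(fit$varcomp["sigma2_a"], 0.05)
  expect_lt(fit$h2, 0.05)
})

test_that("maternal variance is recovered on a nested design", {
  set.seed(53)
  ns <- 40; dps <- 10; k <- 3
  ped <- nested_pedigree(ns, dps, k)
  ndam <- ns * dps; N <- ndam * k
  sire_bv <- rnorm(ns, 0, sqrt(0.3))
  dam_bv <- rnorm(ndam, 0, sqrt(0.3))
  a <- rep(sire_bv, each = dps * k) / 2 + rep(dam_bv, each = k) / 2 +
    rnorm(N, 0, sqrt(0.5 * 0.3))
  m <- rep(rnorm(ndam, 0, sqrt(0.2)), each = k)
  y <- 5 + a + m + rnorm(N, 0, sqrt(0.5))
  dat <- data.frame(animal = ped$animal[-(seq_len(ns + ndam))], value = y)
  fit <- reml_univariate(model_frame(dat, ped, fixed = character(0)),
                         blend_and_build_H(ped))
  expect_lt(abs(fit$varcomp["sigma2_m"] - 0.2), 0.12)
  expect_lt(abs(fit$varcomp["sigma2_a"] - 0.3), 0.25)
  expect_true(is.finite(fit$h2_se))
})

test_that("bivariate REML with a duplicated trait reports correlations of one", {
  set.seed(54)
  ped <- nested_pedigree(20, 5, 3)
  N <- 300
  sire_bv <- rnorm(20, 0, sqrt(0.4))
  a <- rep(sire_bv, each = 15) / 2 + rnorm(N, 0, sqrt(0.75 * 0.4))
  y <- a + rnorm(N, 0, sqrt(0.6))
  lambs <- ped$animal[ped$generation == 1]
  fr1 <- model_frame(data.frame(animal = lambs, value = y), ped, fixed = character(0))
  fr2 <- model_frame(data.frame(animal = lambs, value = y), ped, fixed = character(0))
  rel <- blend_and_build_H(ped)
  fit <- reml_bivariate(fr1, fr2, rel)
  expect_gt(fit$r_g, 0.99)
  expect_gt(fit$r_p, 0.999)
})

test_that("univariate fits are reproduced by a bivariate model with independent traits", {
  set.seed(55)
  ns <- 30; n <- 10
  ped <- half_sib_pedigree(ns, n)
  d1 <- half_sib_phenotypes(ped, ns, n, 0.4, 0.6)
  d2 <- half_sib_phenotypes(ped, ns, n, 0.3, 0.7)
  fr1 <- model_frame(d1, ped, fixed = character(0))
  fr2 <- model_frame(d2, ped, fixed = character(0))
  rel <- blend_and_build_H(ped)
  u1 <- reml_univariate(fr1, rel)
  u2 <- reml_univariate(fr2, rel)
  bv <- reml_bivariate(fr1, fr2, rel)
  expect_lt(abs(bv$Sa[1, 1] - u1$varcomp["sigma2_a"]), 0.05)
  expect_lt(abs(bv$Sa[2, 2] - u2$varcomp["sigma2_a"]), 0.05)
  expect_lt(abs(bv$Se[1, 1] - u1$varcomp["sigma2_e"]), 0.05)
  expect_lt(abs(bv$Se[2, 2] - u2$varcomp["sigma2_e"]), 0.05)
  # independent simulations: genetic correlation consistent with zero
  expect_lt(abs(bv$r_g), max(0.6, 2.5 * max(bv$r_g_se, 0.2, na.rm = TRUE)))
})
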