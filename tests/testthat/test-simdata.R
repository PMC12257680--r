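test_that("simulated pedigrees are valid, deterministic and sire-linked", {
  cfg <- small_sim_config(seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_s3_class(ped, "pedigree")
  expect_silent(validate_pedigree(ped))
  lambs <- ped[!is.na(ped$flock_year), ]
  expect_equal(nrow(lambs), cfg$n_flock_years * cfg$animals_per_group)

  # at least one sire serves both flock-years
  by_sire <- split(lambs$flock_year, lambs$sire)
  expect_true(any(vapply(by_sire, function(x) length(unique(x)) > 1, logical(1))))

  # bitwise determinism under a fixed seed
  ped2 <- simulate_pedigree(small_sim_config(seed = 3))
  expect_identical(ped, ped2)
  expect_error(sim_config(n_flock_years = 0), "counts")
})

test_that("gene dropping obeys Mendelian rules and founder Hardy-Weinberg", {
  ped <- tiny_trio()
  M <- simulate_genotypes(ped, 200, c(0.3, 0.5), seed = 4)
  # offspring dosage bounded by parental alleles
  hom0 <- M[1, ] == 0 & M[2, ] == 0
  expect_true(all(M[3, hom0] == 0))
  hom2 <- M[1, ] == 2 & M[2, ] == 2
  expect_true(all(M[3, hom2] == 2))

  # founder sample frequency ~ binomial around the drawn frequency
  big <- data.frame(animal = 1:10000, sire = 0L, dam = 0L, generation = 0L)
  class(big) <- c("pedigree", "data.frame")
  M2 <- simulate_genotypes(big, 3, c(0.5, 0.5), seed = 5)
  expect_true(all(abs(colMeans(M2) / 2 - 0.5) < 0.02))
  expect_error(simulate_genotypes(ped, 10, c(0, 0.5)), "maf")
})

test_that("breeding values have the family covariance structure", {
  cfg <- small_sim_config(seed = 6)
  # zero additive variance -> all breeding values zero
  cfg0 <- small_sim_config(seed = 6,
    true_variances = list(FD = c(0, 0.05, 0.95), BW = c(0, 0.05, 0.95)),
    genetic_correlation = 0)
  ped <- simulate_pedigree(cfg0)
  eff0 <- simulate_effects(ped, cfg0)
  expect_equal(max(abs(eff0$a_FD)), 0)

  # perfect genetic correlation -> identical standardized breeding values
  cfg1 <- small_sim_config(seed = 7, genetic_correlation = 1)
  ped1 <- simulate_pedigree(cfg1)
  eff1 <- simulate_effects(ped1, cfg1)
  expect_gt(cor(eff1$a_FD, eff1$a_BW, method = "spearman"), 0.9999)

  # full-sib covariance = 0.5 sigma2_a over replicate families
  set.seed(8)
  nfam <- 4000
  ped2 <- data.frame(animal = seq_len(4 * nfam),
                     sire = c(rep(0L, 2 * nfam), rep(seq_len(nfam) * 2 - 1, each = 2)),
                     dam = c(rep(0L, 2 * nfam), rep(seq_len(nfam) * 2, each = 2)),
                     generation = c(rep(0L, 2 * nfam), rep(1L, 2 * nfam)))
  class(ped2) <- c("pedigree", "data.frame")
  ped2$flock_year <- NA_character_
  cfg2 <- small_sim_config(seed = 9,
    true_variances = list(FD = c(1, 0, 0.0001), BW = c(1, 0, 0.0001)),
    genetic_correlation = 0)
  eff2 <- simulate_effects(ped2, cfg2)
  sib1 <- eff2$a_FD[2 * nfam + seq(1, 2 * nfam, by = 2)]
  sib2 <- eff2$a_FD[2 * nfam + seq(2, 2 * nfam, by = 2)]
  expect_lt(abs(cov(sib1, sib2) - 0.5), 3 / sqrt(nfam))
  expect_lt(abs(var(eff2$a_FD[-(seq_len(2 * nfam))]) - 1), 3 / sqrt(nfam))
})

test_that("series generation respects record-count and positivity invariants", {
  cfg <- small_sim_config(seed = 10)
  ped <- simulate_pedigree(cfg)
  eff <- simulate_effects(ped, cfg)
  out <- simulate_series(ped, eff, cfg)
  ser <- out$series
  expect_true(all(ser$value > 0))
  fd_counts <- table(ser$animal[ser$series == "FD"])
  bw_counts <- table(ser$animal[ser$series == "BW"])
  expect_true(all(fd_counts >= 10 & fd_counts <= 27))
  expect_true(all(bw_counts >= 5 & bw_counts <= 20))
  # positions strictly increasing per animal within a series
  for (a in head(unique(ser$animal), 5)) {
    for (sr in c("FD", "BW")) {
      p <- ser$position[ser$animal == a & ser$series == sr]
      expect_true(all(diff(p) > 0))
    }
  }
  # determinism
  out2 <- simulate_series(ped, eff, cfg)
  expect_identical(out$series$value, out2$series$value)
})

test_that("zero susceptibility, zero noise and identity warp give the pure template", {
  cfg <- small_sim_config(seed = 11, phase_sd = 0, noise_sd_fd = 0,
                          noise_sd_bw = 0, dip_flock_year_fraction = 1,
                          sampling_age_sd = 0)
  ped <- simulate_pedigree(cfg)
  eff <- simulate_effects(ped, cfg)
  eff$u_FD[] <- 0
  eff$u_BW[] <- 0
  out <- simulate_series(ped, eff, cfg)
  ser <- out$series[out$series$series == "FD", ]
  # all animals of a flock-year share the template: identical values at
  # matching proportional positions, no dip, no noise
  one_fy <- ser[ser$flock_year == ser$flock_year[1], ]
  # reconstruct the template from one animal and compare against another with
  # the same staple length
  lens <- tapply(one_fy$staple_length, one_fy$animal, unique)
  modal <- as.numeric(names(sort(table(lens), decreasing = TRUE))[1])
  same_len <- names(lens)[lens == modal]
  expect_gte(length(same_len), 2L)
  a1 <- one_fy[one_fy$animal == same_len[1], ]
  a2 <- one_fy[one_fy$animal == same_len[2], ]
  expect_equal(a1$value, a2$value, tolerance = 1e-10)
  # larger susceptibility gives a larger post-weaning drop
  effb <- eff
  effb$u_FD[] <- 2
  outb <- simulate_series(ped, eff = effb, cfg)
  one <- function(res) {
    s <- res$series[res$series$series == "FD", ]
    a <- s[s$animal == s$animal[1], ]
    age <- a$position / a$staple_length[1] * a$sampling_age[1]
    wa <- a$weaning_age[1]
    base <- a$value[max(which(age < wa))]
    min(a$value[age >= wa & age <= wa + 60]) - base
  }
  expect_lt(one(outb), one(out))
})

test_that("phase warp machinery is monotone and vanishes at phase_sd 0", {
  set.seed(12)
  w0 <- woolres:::random_time_warp(300, 0)
  tt <- seq(0, 300, length.out = 51)
  expect_equal(w0(tt), tt)
  w1 <- woolres:::random_time_warp(300, 0.3)
  g <- w1(tt)
  expect_true(all(diff(g) > 0))
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 300, tolerance = 1e-8)
})

test_that("weaning dip bump is C1 with the configured depth", {
  t <- seq(60, 180, by = 0.01)
  d <- woolres:::weaning_dip(t, 90, depth = 2, d1 = 20, d2 = 40)
  expect_equal(min(d), -2, tolerance = 1e-6)
  expect_equal(d[t < 90], rep(0, sum(t < 90)))
  expect_equal(d[t > 150], rep(0, sum(t > 150)))
  # C1: numerical derivative has no jumps larger than O(h)
  dd <- diff(d) / 0.01
  expect_lt(max(abs(diff(dd))), 0.01)
})
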