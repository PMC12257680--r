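# Shared fixtures built in code: tiny pedigrees, smoothing setups and
# half-sib phenotype simulators used across the unit tests.

tiny_trio <- function() {
  ped <- data.frame(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                    generation = c(0L, 0L, 1L))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# s unrelated sires, each with n progeny out of unknown dams
half_sib_pedigree <- function(s, n) {
  ped <- data.frame(animal = seq_len(s + s * n),
                    sire = c(rep(0L, s), rep(seq_len(s), each = n)),
                    dam = 0L,
                    generation = c(rep(0L, s), rep(1L, s * n)))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# balanced half-sib phenotypes: y = mu + sire_bv/2 + mendelian + residual
half_sib_phenotypes <- function(ped, s, n, sigma2_a, sigma2_e, mu = 10) {
  u <- rnorm(s, 0, sqrt(sigma2_a))
  a <- rep(u, each = n) / 2 + rnorm(s * n, 0, sqrt(0.75 * sigma2_a))
  y <- mu + a + rnorm(s * n, 0, sqrt(sigma2_e))
  data.frame(animal = ped$animal[-(seq_len(s))], value = y)
}

# hierarchical pedigree with dams nested in sires (d dams each rearing k lambs)
nested_pedigree <- function(ns, ndam_per_sire, k) {
  ndam <- ns * ndam_per_sire
  N <- ndam * k
  ped <- data.frame(animal = seq_len(ns + ndam + N),
                    sire = c(rep(0L, ns + ndam),
                             rep(seq_len(ns), each = ndam_per_sire * k)),
                    dam = c(rep(0L, ns + ndam),
                            rep(ns + seq_len(ndam), each = k)),
                    generation = c(rep(0L, ns + ndam), rep(1L, N)))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(n_flock_years = 2, animals_per_group = 20, n_sires_per_group = 4,
             n_dams_per_group = 10, n_snps = 50, seed = seed, ...)
}

unit_grid <- function(n = 101) seq(0, 1, length.out = n)
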