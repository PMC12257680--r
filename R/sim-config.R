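#' Configuration for the synthetic flock simulator
#'
#' Bundles every tunable of the synthetic-data generator: population structure,
#' genetic architecture, disturbance regime and measurement design. Defaults
#' emulate a multi-flock Merino yearling study: 41 flock-year groups of about
#' 150 lambs, wool fibre diameter (FD) read at 5 mm increments along the staple
#' (10 to 27 records per animal), body weight (BW) recorded 5 to 20 times
#' between birth and wool sampling at roughly ten months, and weaning at a mean
#' age of 90 days (range 62 to 119).
#'
#' The latent susceptibility of each animal (one scalar per series, FD and BW)
#' scales both the weaning collapse-and-recovery dip and the random transient
#' perturbations. Susceptibility is itself a heritable trait with additive,
#' maternal permanent environmental and residual components, so that
#' heritability recovery of downstream resilience indicators can be validated
#' against a known truth.
#'
#' @param n_flock_years number of flock-year contemporary groups.
#' @param animals_per_group phenotyped lambs per flock-year.
#' @param n_sires_per_group sires mated within each flock-year; sires are drawn
#'   from a shared pool so that flock-years are linked by common sires.
#' @param n_dams_per_group dams per flock-year (each dam rears 1-2 lambs).
#' @param n_snps number of simulated SNPs for the genomic matrix.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param true_variances named list with entries `FD` and `BW`, each a numeric
#'   vector `c(sigma2_a, sigma2_m, sigma2_e)` for log-susceptibility. Defaults
#'   give h2 = 0.10 with a maternal fraction of 0.05.
#' @param genetic_correlation additive genetic correlation between FD and BW
#'   log-susceptibility.
#' @param weaning_day_mean,weaning_day_sd,weaning_day_range weaning-age
#'   distribution in days (truncated normal).
#' @param dip_depth_fd,dip_depth_bw depth of the weaning dip at susceptibility
#'   1, in µm (FD) and kg (BW).
#' @param dip_response_days,dip_recovery_days durations of the collapse and
#'   recovery ramps of the weaning dip, days.
#' @param dip_flock_year_fraction fraction of flock-years in which a weaning
#'   dip is present at all (management in the rest buffers the event).
#' @param fd_season_amp amplitude of the seasonal fibre-diameter trend, µm;
#'   the structured background the weaning-window detector must not mistake
#'   for a disturbance.
#' @param perturbation_rate expected number of random transient disturbances
#'   per 100 days of growth.
#' @param perturbation_amp_fd,perturbation_amp_bw sd of the (signed) amplitude
#'   of a random disturbance at susceptibility 1, µm / kg.
#' @param phase_sd magnitude (sd of log-rate coefficients) of the individual
#'   monotone time warp; 0 disables phase variation.
#' @param noise_sd_fd,noise_sd_bw iid measurement noise sd, µm / kg.
#' @param fd_step staple increment between FD readings, mm.
#' @param fd_records_range,bw_records_range admissible record counts.
#' @param sampling_age_mean,sampling_age_sd wool sampling age, days.
#' @param seed integer seed driving all randomness (streams are split per
#'   generator stage by fixed offsets).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_flock_years = 41L,
                       animals_per_group = 150L,
                       n_sires_per_group = 10L,
                       n_dams_per_group = 100L,
                       n_snps = 500L,
                       maf_range = c(0.05, 0.5),
                       true_variances = list(FD = c(sigma2_a = 0.10, sigma2_m = 0.05, sigma2_e = 0.85),
                                             BW = c(sigma2_a = 0.10, sigma2_m = 0.05, sigma2_e = 0.85)),
                       genetic_correlation = 0.5,
                       weaning_day_mean = 90,
                       weaning_day_sd = 10,
                       weaning_day_range = c(62, 119),
                       dip_depth_fd = 2.0,
                       dip_depth_bw = 2.0,
                       dip_response_days = 20,
                       dip_recovery_days = 40,
                       dip_flock_year_fraction = 17 / 41,
                       fd_season_amp = 0.8,
                       perturbation_rate = 1.2,
                       perturbation_amp_fd = 1.5,
                       perturbation_amp_bw = 1.2,
                       phase_sd = 0.10,
                       noise_sd_fd = 0.4,
                       noise_sd_bw = 0.6,
                       fd_step = 5,
                       fd_records_range = c(10L, 27L),
                       bw_records_range = c(5L, 20L),
                       sampling_age_mean = 300,
                       sampling_age_sd = 15,
                       seed = 1L) {
  cfg <- list(
    n_flock_years = as.integer(n_flock_years),
    animals_per_group = as.integer(animals_per_group),
    n_sires_per_group = as.integer(n_sires_per_group),
    n_dams_per_group = as.integer(n_dams_per_group),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    true_variances = lapply(true_variances, function(v) {
      v <- as.numeric(v)
      names(v) <- c("sigma2_a", "sigma2_m", "sigma2_e")
      v
    }),
    genetic_correlation = as.numeric(genetic_correlation),
    weaning_day_mean = weaning_day_mean,
    weaning_day_sd = weaning_day_sd,
    weaning_day_range = as.numeric(weaning_day_range),
    dip_depth_fd = dip_depth_fd,
    dip_depth_bw = dip_depth_bw,
    dip_response_days = dip_response_days,
    dip_recovery_days = dip_recovery_days,
    dip_flock_year_fraction = dip_flock_year_fraction,
    fd_season_amp = fd_season_amp,
    perturbation_rate = perturbation_rate,
    perturbation_amp_fd = perturbation_amp_fd,
    perturbation_amp_bw = perturbation_amp_bw,
    phase_sd = phase_sd,
    noise_sd_fd = noise_sd_fd,
    noise_sd_bw = noise_sd_bw,
    fd_step = fd_step,
    fd_records_range = as.integer(fd_records_range),
    bw_records_range = as.integer(bw_records_range),
    sampling_age_mean = sampling_age_mean,
    sampling_age_sd = sampling_age_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_flock_years, cfg$animals_per_group, cfg$n_sires_per_group,
              cfg$n_dams_per_group)
  if (any(counts < 1L)) stop("all population counts must be >= 1")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5] and be ordered")
  }
  for (tr in names(cfg$true_variances)) {
    v <- cfg$true_variances[[tr]]
    if (any(v < 0) || sum(v) <= 0) stop("true variances must be non-negative with positive total")
  }
  if (abs(cfg$genetic_correlation) > 1) stop("genetic correlation must be in [-1, 1]")
  Sg <- sim_genetic_cov(cfg)
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("genetic covariance matrix is not positive semi-definite")
  if (cfg$phase_sd < 0) stop("phase_sd must be >= 0")
  if (diff(cfg$weaning_day_range) < 0) stop("weaning_day_range must be ordered")
  invisible(cfg)
}

# Additive genetic covariance matrix of (FD, BW) log-susceptibility.
sim_genetic_cov <- function(cfg) {
  sa <- sqrt(c(cfg$true_variances$FD["sigma2_a"], cfg$true_variances$BW["sigma2_a"]))
  S <- diag(sa) %*% matrix(c(1, cfg$genetic_correlation,
                             cfg$genetic_correlation, 1), 2) %*% diag(sa)
  dimnames(S) <- list(c("FD", "BW"), c("FD", "BW"))
  S
}
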