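#' Simulate longitudinal fibre-diameter and body-weight series
#'
#' Builds, for every lamb in the pedigree, a fibre diameter (FD) trajectory
#' along the wool staple and a body weight (BW) trajectory over age. Each
#' underlying signal is a flock-year template (slow seasonal trend for FD,
#' Gompertz growth for BW) plus a C1 weaning collapse-and-recovery dip and
#' random transient perturbations, both scaled by the animal's susceptibility,
#' composed with an individual smooth monotone time warp (phase variation) and
#' observed with iid measurement noise at irregular positions.
#'
#' FD is read at `fd_step` mm increments from the staple tip (position 0 =
#' birth end); position p corresponds to age `p / staple_length * sampling_age`
#' so the weaning dip appears proportionally along the staple. BW is recorded
#' at a flock-year measurement schedule (birth, then roughly 3-weekly from
#' weaning) with per-animal missingness.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param effects true effects from [simulate_effects()].
#' @param config a [sim_config()].
#' @return list with `series` (long `data.frame`: `animal`, `series`
#'   (`"FD"`/`"BW"`), `position`, `value`, `flock_year`, `sex`, `brt`,
#'   `weaning_age`, `staple_length`, `sampling_age`), `truth` (per-animal true
#'   susceptibilities, breeding values and per-flock-year dip indicator) and
#'   `flock_years` (per-group dip indicator and mean weaning age).
#' @export
simulate_series <- function(ped, effects, config) {
  validate_pedigree(ped)
  stopifnot(inherits(config, "sim_config"))
  lambs <- lamb_cohort(ped)
  if (!all(lambs$animal %in% effects$animal)) stop("effects missing for some animals")
  eff <- effects[match(lambs$animal, effects$animal), ]

  with_stage_seed(config$seed, 404L, {
    g_labels <- unique(lambs$flock_year)
    n_g <- length(g_labels)
    dip_present <- setNames(runif(n_g) < config$dip_flock_year_fraction, g_labels)
    # flock-year template parameters. Lambing is seasonal, so the FD seasonal
    # cycle is calendar-locked across flock-years (small management jitter):
    # the seasonal trough sits near the end of the growth period (~280 d),
    # well past the weaning window.
    fd_level <- setNames(rnorm(n_g, 17, 0.8), g_labels)
    fd_season_phase <- setNames(rnorm(n_g, -6, 10), g_labels)
    bw_amax <- setNames(rnorm(n_g, 46, 2), g_labels)

    n <- nrow(lambs)
    weaning_age <- pmin(pmax(rnorm(n, config$weaning_day_mean, config$weaning_day_sd),
                             config$weaning_day_range[1]), config$weaning_day_range[2])
    sampling_age <- round(pmin(pmax(rnorm(n, config$sampling_age_mean, config$sampling_age_sd),
                                    210), 390))
    # body-weight occasions are scheduled per flock-year (the whole group is
    # mustered together), truncated at the group's earliest wool sampling
    bw_sched <- lapply(g_labels, function(fy) {
      Tmin <- min(sampling_age[lambs$flock_year == fy])
      c(0, seq(90, Tmin, by = 21))
    })
    names(bw_sched) <- g_labels
    # staple length from per-animal growth rate, snapped to the 5 mm grid and
    # clipped so FD record counts stay inside the admissible range
    rate <- rnorm(n, 0.22, 0.025)
    nrec_fd <- round(rate * sampling_age / config$fd_step) + 1L
    nrec_fd <- pmin(pmax(nrec_fd, config$fd_records_range[1]), config$fd_records_range[2])
    staple_length <- (nrec_fd - 1L) * config$fd_step
    brt <- sample(c("11", "21", "22"), n, replace = TRUE, prob = c(0.35, 0.25, 0.40))

    out <- vector("list", n)
    truth <- data.frame(animal = lambs$animal, flock_year = lambs$flock_year,
                        u_FD = eff$u_FD, u_BW = eff$u_BW,
                        a_FD = eff$a_FD, a_BW = eff$a_BW,
                        weaning_age = weaning_age,
                        dip_present = unname(dip_present[lambs$flock_year]))

    for (i in seq_len(n)) {
      fy <- lambs$flock_year[i]
      Ti <- sampling_age[i]
      warp <- random_time_warp(Ti, config$phase_sd)

      sig_fd <- make_signal(
        template = function(t) fd_level[fy] + 0.004 * t +
          config$fd_season_amp * sin(2 * pi * (t + fd_season_phase[fy]) / 365),
        T_end = Ti, weaning = weaning_age[i],
        dip = dip_present[fy] * config$dip_depth_fd * eff$u_FD[i],
        d1 = config$dip_response_days, d2 = config$dip_recovery_days,
        pert_rate = config$perturbation_rate,
        pert_amp = config$perturbation_amp_fd * eff$u_FD[i]
      )
      sig_bw <- make_signal(
        template = function(t) bw_amax[fy] * exp(-2.3 * exp(-0.008 * t)),
        T_end = Ti, weaning = weaning_age[i],
        dip = dip_present[fy] * config$dip_depth_bw * eff$u_BW[i],
        d1 = config$dip_response_days, d2 = config$dip_recovery_days,
        pert_rate = config$perturbation_rate,
        pert_amp = config$perturbation_amp_bw * eff$u_BW[i]
      )

      # FD observations along the staple
      pos_fd <- seq(0, staple_length[i], by = config$fd_step)
      age_fd <- pos_fd / staple_length[i] * Ti
      val_fd <- sig_fd(warp(age_fd)) + rnorm(length(pos_fd), 0, config$noise_sd_fd)
      val_fd <- pmax(val_fd, 0.5)

      # BW observations on the flock-year schedule (birth, then ~3-weekly)
      sched <- bw_sched[[fy]]
      keep <- c(TRUE, runif(length(sched) - 1) > 0.12)
      ages_bw <- sched[keep]
      if (length(ages_bw) < config$bw_records_range[1]) ages_bw <- sched
      if (length(ages_bw) > config$bw_records_range[2]) {
        ages_bw <- ages_bw[sort(sample.int(length(ages_bw), config$bw_records_range[2]))]
      }
      val_bw <- sig_bw(warp(ages_bw)) + rnorm(length(ages_bw), 0, config$noise_sd_bw)
      val_bw <- pmax(val_bw, 0.5)

      base <- list(animal = lambs$animal[i], flock_year = fy, sex = lambs$sex[i],
                   brt = brt[i], weaning_age = weaning_age[i],
                   sampling_age = Ti)
      out[[i]] <- rbind(
        data.frame(base, series = "FD", position = pos_fd, value = val_fd,
                   staple_length = staple_length[i]),
        data.frame(base, series = "BW", position = ages_bw, value = val_bw,
                   staple_length = NA_real_)
      )
    }
    series <- do.call(rbind, out)
    rownames(series) <- NULL
    series <- series[, c("animal", "series", "position", "value", "flock_year",
                         "sex", "brt", "weaning_age", "staple_length", "sampling_age")]
    fy_tab <- data.frame(flock_year = g_labels,
                         dip_present = unname(dip_present[g_labels]),
                         mean_weaning_age = as.numeric(tapply(weaning_age, lambs$flock_year,
                                                              mean)[g_labels]))
    list(series = series, truth = truth, flock_years = fy_tab)
  })
}

# Underlying noiseless signal in canonical (unwarped) time: template + weaning
# dip + random transient perturbations. Returns a vectorized function of age.
make_signal <- function(template, T_end, weaning, dip, d1, d2, pert_rate, pert_amp) {
  n_pert <- if (pert_rate > 0 && pert_amp != 0) rpois(1, pert_rate * T_end / 100) else 0L
  pc <- runif(n_pert, 0, T_end)
  pa <- rnorm(n_pert, 0, 1) * pert_amp
  pd <- runif(n_pert, 10, 30)
  function(t) {
    y <- template(t)
    if (dip != 0) y <- y + weaning_dip(t, weaning, dip, d1, d2)
    if (n_pert > 0) {
      for (k in seq_len(n_pert)) y <- y + pa[k] * exp(-0.5 * ((t - pc[k]) / (pd[k] / 2))^2)
    }
    y
  }
}

# C1 collapse-and-recovery bump: cosine down-ramp over d1 days reaching -depth,
# cosine recovery over d2 days back to zero. Derivative vanishes at all joins.
weaning_dip <- function(t, t_w, depth, d1, d2) {
  y <- numeric(length(t))
  in1 <- t >= t_w & t < t_w + d1
  in2 <- t >= t_w + d1 & t <= t_w + d1 + d2
  y[in1] <- -depth * (1 - cos(pi * (t[in1] - t_w) / d1)) / 2
  y[in2] <- -depth * (1 + cos(pi * (t[in2] - t_w - d1) / d2)) / 2
  y
}

# Random smooth monotone time warp on [0, T]: the normalized integral of a
# positive log-Gaussian rate process. phase_sd = 0 gives the identity exactly.
random_time_warp <- function(T_end, phase_sd) {
  if (phase_sd == 0) return(function(t) t)
  z <- rnorm(3, 0, phase_sd)
  fine <- seq(0, 1, length.out = 401)
  v <- exp(z[1] * sin(pi * fine) + z[2] * sin(2 * pi * fine) + z[3] * sin(3 * pi * fine))
  cumv <- c(0, cumsum((v[-1] + v[-length(v)]) / 2))
  gam <- cumv / cumv[length(cumv)]
  function(t) approx(fine * T_end, gam * T_end, xout = pmin(pmax(t, 0), T_end))$y
}
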