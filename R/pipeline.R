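#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic population (ignored
#'   when pre-built inputs are supplied to [run_pipeline()]).
#' @param fd_smooth,bw_smooth [smoothing_config()]s per series. Defaults:
#'   order 4 / step 1 mm for fibre diameter, order 3 / step 10 days with extra
#'   knots at 30 and 60 days for body weight (the pre-weaning region is
#'   sparse because lambs are not weighed between birth and weaning). The FD
#'   default uses `lambda_smooth = 50`: the curvature penalty is dimensional
#'   and at the synthetic ~65 mm staple scale this matches the flexibility
#'   that heavier penalties give on longer real staples; pass
#'   `smoothing_config(order = 4)` for the conventional 2500.
#' @param lambda_fd,lambda_bw default alignment penalties (0.2 / 0.6).
#' @param lambda_grid optional vector of additional alignment penalties for
#'   sensitivity analyses; the defaults are always included.
#' @param use_genotypes build H from simulated genotypes (otherwise H = A).
#' @param genotyped_fraction fraction of phenotyped lambs genotyped.
#' @param prominence_sd_fraction weaning-window prominence threshold as a
#'   fraction of the group's cross-sectional (between-animal) sd of the
#'   aligned curves. The mean curve of a standardized series is nearly flat,
#'   so its own sd is not a usable yardstick.
#' @param window_span_fraction search span after the weaning anchor as a
#'   fraction of the domain (default 0.3: about 90 days, the scale of the
#'   collapse-and-recovery ramps).
#' @param alpha H-matrix blending weight.
#' @param staple_origin `"birth"` (default) when position 0 of the FD profile
#'   is the staple tip laid down at birth, `"sampling"` when the instrument
#'   reports positions from the cut end; in the latter case FD positions are
#'   reflected so that the analysis always runs in birth-forward time.
#' @param out_dir optional directory for the CSV outputs and manifest.
#' @param seed integer seed (propagated into `sim` when not already set).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            fd_smooth = smoothing_config(order = 4L, lambda_smooth = 50,
                                                         prediction_step = 1),
                            bw_smooth = smoothing_config(order = 3L, prediction_step = 10,
                                                         extra_knots = c(30, 60)),
                            lambda_fd = 0.2, lambda_bw = 0.6,
                            lambda_grid = NULL,
                            use_genotypes = FALSE,
                            genotyped_fraction = 0.6,
                            prominence_sd_fraction = 0.3,
                            window_span_fraction = 0.3,
                            alpha = 0.95,
                            staple_origin = c("birth", "sampling"),
                            out_dir = NULL,
                            seed = NULL) {
  staple_origin <- match.arg(staple_origin)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  lg_fd <- sort(unique(c(lambda_fd, lambda_grid)))
  lg_bw <- sort(unique(c(lambda_bw, lambda_grid)))
  structure(list(sim = sim, fd_smooth = fd_smooth, bw_smooth = bw_smooth,
                 lambda_fd = lambda_fd, lambda_bw = lambda_bw,
                 lambda_grid_fd = lg_fd, lambda_grid_bw = lg_bw,
                 use_genotypes = use_genotypes,
                 genotyped_fraction = genotyped_fraction,
                 prominence_sd_fraction = prominence_sd_fraction,
                 window_span_fraction = window_span_fraction,
                 alpha = alpha, staple_origin = staple_origin,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the resilience pipeline end to end
#'
#' Orchestrates simulate, standardize, smooth, align, traits (indicators +
#' outlier filtering) and varcomp as resumable stages. Each stage consumes the
#' previous stage's output; when `config$out_dir` is set, every stage writes
#' its documented CSV and a manifest with content hashes is produced.
#'
#' @param config a [pipeline_config()].
#' @param stages which stages to run, in order; default all. Must be a
#'   contiguous prefix-respecting subset: each requested stage needs its
#'   upstream either in `stages` or supplied via `state`.
#' @param state optional partial result of a previous call (for resuming).
#' @param traits_for_varcomp trait names sent to REML (default `"Lnvar"` to
#'   keep routine runs fast; any of the seven indicator names are valid).
#' @return object of class `pipeline_result`: a list with entries per stage
#'   (`sim`, `standardized`, `smooth`, `alignment`, `traits`, `varcomp`) plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "standardize", "smooth", "align",
                                    "traits", "varcomp"),
                         state = NULL,
                         traits_for_varcomp = "Lnvar") {
  res <- if (is.null(state)) list() else state
  res$config <- config
  all_stages <- c("simulate", "standardize", "smooth", "align", "traits", "varcomp")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop("stage '", stage, "' requires upstream output '", what,
           "': run that stage first or pass it via `state`")
    }
    res[[what]]
  }

  if ("simulate" %in% stages) {
    ped <- simulate_pedigree(config$sim)
    eff <- simulate_effects(ped, config$sim)
    ser <- simulate_series(ped, eff, config$sim)
    geno <- NULL
    if (config$use_genotypes) {
      lambs <- lamb_cohort(ped)
      geno_all <- simulate_genotypes(ped, config$sim$n_snps, config$sim$maf_range,
                                     seed = config$sim$seed)
      keep <- with_stage_seed(config$sim$seed, 505L, {
        sample(lambs$animal, round(config$genotyped_fraction * nrow(lambs)))
      })
      geno <- geno_all[as.character(keep), , drop = FALSE]
    }
    res$sim <- list(pedigree = ped, effects = eff, series = ser$series,
                    truth = ser$truth, flock_years = ser$flock_years,
                    genotypes = geno)
  }

  if ("standardize" %in% stages) {
    sim <- need("sim", "standardize")
    ser <- sim$series
    if (identical(config$staple_origin, "sampling")) {
      fd <- ser$series == "FD"
      ser$position[fd] <- ser$staple_length[fd] - ser$position[fd]
      ser <- ser[order(ser$animal, ser$series, ser$position), , drop = FALSE]
      rownames(ser) <- NULL
    }
    res$standardized <- standardize_raw(ser, on_small = "drop")
  }

  if ("smooth" %in% stages) {
    std <- need("standardized", "smooth")
    res$smooth <- smooth_stage(std, config)
  }

  if ("align" %in% stages) {
    sm <- need("smooth", "align")
    res$alignment <- align_stage(sm, config)
  }

  if ("traits" %in% stages) {
    al <- need("alignment", "traits")
    sm <- need("smooth", "traits")
    res$traits <- traits_stage(al, sm, config)
  }

  if ("varcomp" %in% stages) {
    tr <- need("traits", "varcomp")
    sim <- need("sim", "varcomp")
    res$varcomp <- varcomp_stage(tr, sim, config, traits_for_varcomp)
  }

  if (!is.null(config$out_dir)) {
    res$manifest <- write_pipeline_outputs(res, config$out_dir)
  }
  class(res) <- "pipeline_result"
  res
}

# Smooth stage: per flock-year and series, pooled quantile knots, per-animal
# penalized fits on the animal's own domain, evaluated on a proportional
# common grid scaled to the group median domain length.
smooth_stage <- function(std, config) {
  out <- list()
  for (series in c("FD", "BW")) {
    scfg <- if (series == "FD") config$fd_smooth else config$bw_smooth
    sdat <- std[std$series == series, , drop = FALSE]
    if (!nrow(sdat)) next
    for (fy in unique(sdat$flock_year)) {
      g <- sdat[sdat$flock_year == fy, , drop = FALSE]
      animals <- unique(g$animal)
      if (length(animals) < 2L) next
      dom_len <- vapply(animals, function(a) {
        gi <- g[g$animal == a, ]
        if (series == "FD") gi$staple_length[1] else gi$sampling_age[1]
      }, numeric(1))
      L_g <- median(dom_len)
      # a sparse measurement schedule can offer fewer distinct positions than
      # the requested quantile count; use what the data supports
      nq <- min(scfg$n_quantile_knots, length(unique(g$position)) - 1L)
      knots_g <- quantile_knots(g$position, nq,
                                extra_knots = scfg$extra_knots,
                                domain = c(0, max(dom_len)))
      n_t <- max(31L, round(L_g / scfg$prediction_step) + 1L)
      p_grid <- seq(0, 1, length.out = n_t)
      curves <- matrix(NA_real_, n_t, length(animals),
                       dimnames = list(NULL, animals))
      for (j in seq_along(animals)) {
        gi <- g[g$animal == animals[j], ]
        Lj <- dom_len[j]
        kj <- sort(unique(c(0, knots_g[knots_g > 0 & knots_g < Lj], Lj)))
        fit <- fit_penalized_spline(gi$position, gi$value, kj, scfg)
        curves[, j] <- evaluate_curve(fit, p_grid * Lj)
      }
      meta <- g[!duplicated(g$animal),
                c("animal", "flock_year", "sex", "brt", "weaning_age",
                  "staple_length", "sampling_age")]
      out[[paste(series, fy, sep = ":")]] <-
        list(series = series, flock_year = fy, grid = p_grid * L_g,
             L_g = L_g, curves = curves, meta = meta, knots = knots_g)
    }
  }
  out
}

# Align stage: elastic alignment of every group at the configured lambdas.
align_stage <- function(sm, config) {
  lapply(sm, function(g) {
    lambdas <- if (g$series == "FD") config$lambda_grid_fd else config$lambda_grid_bw
    align_group(g$curves, g$grid, lambda_grid = lambdas,
                ids = colnames(g$curves), flock_year = g$flock_year)
  })
}

# Traits stage: indicators per group per lambda, then 3-SD outlier filtering
# within flock-year (per trait, per series, per lambda).
traits_stage <- function(al, sm, config) {
  rows <- list()
  windows <- list()
  for (key in names(al)) {
    g <- sm[[key]]
    ga <- al[[key]]
    meta <- g$meta
    anchor <- if (g$series == "FD") {
      mean(map_age_to_staple(meta$weaning_age, meta$sampling_age, g$L_g))
    } else {
      mean(meta$weaning_age)
    }
    for (lam in attr(ga, "lambda_grid")) {
      entry <- ga[[paste0("lambda_", lam)]]
      xsec_sd <- mean(apply(entry$aligned, 1, sd))
      gi <- group_indicators(entry$aligned, entry$mean_curve, g$grid, anchor,
                             series = g$series, flock_year = g$flock_year,
                             search_span = config$window_span_fraction * diff(range(g$grid)),
                             prominence = config$prominence_sd_fraction * xsec_sd)
      gi$traits$lambda <- lam
      rows[[paste(key, lam)]] <- gi$traits
      windows[[paste(key, lam)]] <-
        data.frame(series = g$series, flock_year = g$flock_year, lambda = lam,
                   detected = gi$window$detected, t_w = gi$window$t_w,
                   t_min = if (gi$window$detected) gi$window$t_min else NA_real_,
                   t_max = if (gi$window$detected) gi$window$t_max else NA_real_)
    }
  }
  traits <- do.call(rbind, rows)
  rownames(traits) <- NULL
  filtered <- list()
  for (series in unique(traits$series)) {
    for (lam in unique(traits$lambda[traits$series == series])) {
      sub <- traits[traits$series == series & traits$lambda == lam, ]
      filtered[[paste(series, lam)]] <- remove_outliers(sub)$traits
    }
  }
  traits <- do.call(rbind, filtered)
  rownames(traits) <- NULL
  windows <- do.call(rbind, windows)
  rownames(windows) <- NULL
  list(traits = traits, windows = windows)
}

# Varcomp stage: univariate REML per requested trait x series at the default
# lambda of each series.
varcomp_stage <- function(tr, sim, config, trait_names) {
  rel <- blend_and_build_H(sim$pedigree, G = if (!is.null(sim$genotypes)) {
    build_G(sim$genotypes)
  } else NULL, alpha = config$alpha)
  meta <- sim$series[!duplicated(sim$series$animal),
                     c("animal", "flock_year", "sex", "brt")]
  fits <- list()
  for (series in unique(tr$traits$series)) {
    lam <- if (series == "FD") config$lambda_fd else config$lambda_bw
    for (trait in trait_names) {
      sub <- tr$traits[tr$traits$series == series & tr$traits$trait == trait &
                         tr$traits$lambda == lam, ]
      dat <- merge(sub[, c("animal", "value")], meta, by = "animal")
      if (sum(!is.na(dat$value)) < 30L) next
      frame <- model_frame(dat, sim$pedigree)
      fits[[paste(series, trait, sep = "_")]] <-
        tryCatch(reml_univariate(frame, rel),
                 error = function(e) structure(list(error = conditionMessage(e)),
                                               class = "reml_error"))
    }
  }
  list(rel = rel, fits = fits)
}

#' Cross-lambda sensitivity of a resilience indicator
#'
#' Genetic and phenotypic correlations between the same indicator computed
#' under different alignment penalties, via bivariate REML: the analogue of
#' checking that trait definitions are stable over the lambda grid.
#'
#' @param result a `pipeline_result` whose traits stage ran with at least two
#'   lambdas for the requested series.
#' @param trait indicator name (default `"Lnvar"`).
#' @param series `"FD"` or `"BW"`.
#' @return `data.frame` with one row per lambda pair: `lambda1`, `lambda2`,
#'   `r_g`, `r_g_se`, `r_p`, `r_p_se`.
#' @export
lambda_sensitivity <- function(result, trait = "Lnvar", series = "FD") {
  tr <- result$traits$traits
  tr <- tr[tr$series == series & tr$trait == trait, ]
  lambdas <- sort(unique(tr$lambda))
  if (length(lambdas) < 2L) stop("need traits computed for at least 2 lambdas")
  sim <- result$sim
  meta <- sim$series[!duplicated(sim$series$animal),
                     c("animal", "flock_year", "sex", "brt")]
  rel <- blend_and_build_H(sim$pedigree)
  frame_for <- function(lam) {
    sub <- tr[tr$lambda == lam, c("animal", "value")]
    model_frame(merge(sub, meta, by = "animal"), sim$pedigree)
  }
  frames <- lapply(lambdas, frame_for)
  out <- list()
  for (i in seq_along(lambdas)) {
    for (j in seq_along(lambdas)) {
      if (j <= i) next
      fit <- reml_bivariate(frames[[i]], frames[[j]], rel)
      out[[length(out) + 1L]] <-
        data.frame(trait = trait, series = series,
                   lambda1 = lambdas[i], lambda2 = lambdas[j],
                   r_g = fit$r_g, r_g_se = fit$r_g_se,
                   r_p = fit$r_p, r_p_se = fit$r_p_se)
    }
  }
  do.call(rbind, out)
}

#' Summary tables of a pipeline run
#'
#' Descriptive statistics and heritabilities per trait x series (one row
#' each), and the variance components behind them, assembled from the run's
#' own outputs.
#'
#' @param result a `pipeline_result` including the varcomp stage.
#' @return list: `h2_table` (`data.frame`: series, trait, n, mean, sd, min,
#'   max, sigma2_a, sigma2_m, sigma2_e, h2, h2_se) and `windows` (weaning
#'   window registry).
#' @export
report_tables <- function(result) {
  tr <- result$traits$traits
  rows <- list()
  for (nm in names(result$varcomp$fits)) {
    fit <- result$varcomp$fits[[nm]]
    parts <- strsplit(nm, "_")[[1]]
    series <- parts[1]; trait <- paste(parts[-1], collapse = "_")
    lam <- if (series == "FD") result$config$lambda_fd else result$config$lambda_bw
    v <- tr$value[tr$series == series & tr$trait == trait & tr$lambda == lam]
    v <- v[!is.na(v)]
    if (inherits(fit, "reml_error")) {
      rows[[nm]] <- data.frame(series = series, trait = trait, n = length(v),
                               mean = mean(v), sd = sd(v), min = min(v), max = max(v),
                               sigma2_a = NA, sigma2_m = NA, sigma2_e = NA,
                               h2 = NA, h2_se = NA)
    } else {
      rows[[nm]] <- data.frame(series = series, trait = trait, n = length(v),
                               mean = mean(v), sd = sd(v), min = min(v), max = max(v),
                               sigma2_a = fit$varcomp[1], sigma2_m = fit$varcomp[2],
                               sigma2_e = fit$varcomp[3], h2 = fit$h2,
                               h2_se = fit$h2_se)
    }
  }
  h2_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(series = character(0), trait = character(0))
  rownames(h2_table) <- NULL
  list(h2_table = h2_table, windows = result$traits$windows)
}
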