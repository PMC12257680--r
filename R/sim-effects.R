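#' Simulate true genetic and environmental effects for susceptibility
#'
#' Draws correlated additive breeding values for FD and BW log-susceptibility
#' recursively down the pedigree (founder draw; offspring = parent average +
#' Mendelian sampling deviation with variance reduced by parental inbreeding),
#' maternal permanent environmental effects independently per dam, and residual
#' environmental deviations per lamb. The susceptibility scalar that multiplies
#' disturbance amplitudes in [simulate_series()] is
#' `u = exp(a + m + e)` so the true h2 of log-susceptibility equals the
#' configured ratio.
#'
#' @param ped a pedigree from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return `data.frame` with one row per pedigree animal: breeding values
#'   `a_FD`, `a_BW`; for lambs additionally maternal effects `m_FD`, `m_BW`
#'   (copied from the dam), residuals `e_FD`, `e_BW` and susceptibilities
#'   `u_FD`, `u_BW` (`NA` for non-phenotyped ancestors).
#' @export
simulate_effects <- function(ped, config) {
  validate_pedigree(ped)
  stopifnot(inherits(config, "sim_config"))
  Sg <- sim_genetic_cov(config)
  ev <- eigen(Sg, symmetric = TRUE)
  if (any(ev$values < -1e-10)) stop("genetic covariance must be positive semi-definite")
  # matrix square root (handles the r_g = 1 singular case)
  Sg_half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)

  with_stage_seed(config$seed, 303L, {
    n <- nrow(ped)
    spos <- match(ped$sire, ped$animal)
    dpos <- match(ped$dam, ped$animal)
    Fi <- pedigree_inbreeding(ped)

    a <- matrix(0, n, 2, dimnames = list(ped$animal, c("FD", "BW")))
    for (i in seq_len(n)) {
      s <- spos[i]; d <- dpos[i]
      if (is.na(s) && is.na(d)) {
        a[i, ] <- Sg_half %*% rnorm(2)
      } else {
        pa <- 0
        vms <- 1
        if (!is.na(s) && !is.na(d)) {
          pa <- (a[s, ] + a[d, ]) / 2
          vms <- 0.5 - 0.25 * (Fi[s] + Fi[d])
        } else if (!is.na(s)) {
          pa <- a[s, ] / 2
          vms <- 0.75 - 0.25 * Fi[s]
        } else {
          pa <- a[d, ] / 2
          vms <- 0.75 - 0.25 * Fi[d]
        }
        a[i, ] <- pa + sqrt(vms) * (Sg_half %*% rnorm(2))
      }
    }

    # maternal permanent environmental effects: one draw per dam per series
    dams <- unique(ped$dam[ped$dam != 0L])
    m_fd <- setNames(rnorm(length(dams), 0, sqrt(config$true_variances$FD["sigma2_m"])), dams)
    m_bw <- setNames(rnorm(length(dams), 0, sqrt(config$true_variances$BW["sigma2_m"])), dams)

    lamb <- !is.na(ped$flock_year)
    eff <- data.frame(animal = ped$animal,
                      a_FD = a[, "FD"], a_BW = a[, "BW"],
                      m_FD = NA_real_, m_BW = NA_real_,
                      e_FD = NA_real_, e_BW = NA_real_,
                      u_FD = NA_real_, u_BW = NA_real_)
    nl <- sum(lamb)
    eff$m_FD[lamb] <- m_fd[as.character(ped$dam[lamb])]
    eff$m_BW[lamb] <- m_bw[as.character(ped$dam[lamb])]
    eff$m_FD[lamb][is.na(eff$m_FD[lamb])] <- 0
    eff$m_BW[lamb][is.na(eff$m_BW[lamb])] <- 0
    eff$e_FD[lamb] <- rnorm(nl, 0, sqrt(config$true_variances$FD["sigma2_e"]))
    eff$e_BW[lamb] <- rnorm(nl, 0, sqrt(config$true_variances$BW["sigma2_e"]))
    eff$u_FD[lamb] <- exp(eff$a_FD[lamb] + eff$m_FD[lamb] + eff$e_FD[lamb])
    eff$u_BW[lamb] <- exp(eff$a_BW[lamb] + eff$m_BW[lamb] + eff$e_BW[lamb])
    eff
  })
}

#' Pedigree inbreeding coefficients
#'
#' Computes F for every animal by recursive kinship with memoisation
#' (F_i = kinship of the parents). Suitable for the shallow pedigrees the
#' simulator produces; [build_A()] provides the full relationship matrix.
#'
#' @param ped a valid pedigree.
#' @return numeric vector of inbreeding coefficients in pedigree order.
#' @export
pedigree_inbreeding <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  spos <- match(ped$sire, ped$animal)  # NA when unknown
  dpos <- match(ped$dam, ped$animal)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(spos[i], dpos[i]))
    } else {
      # j is the later-born animal: recurse through its parents
      0.5 * (phi(i, spos[j]) + phi(i, dpos[j]))
    }
    cache[[key]] <- val
    val
  }
  vapply(seq_len(n), function(i) phi(spos[i], dpos[i]), numeric(1))
}
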