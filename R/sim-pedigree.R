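#' Simulate a three-generation pedigree with sire linkage across flock-years
#'
#' Generates founders (generation 0), parents (generation 1: a shared sire pool
#' and per-group dams) and the phenotyped lamb cohort (generation 2). Each
#' flock-year is serviced by sires sampled from a pool roughly half the size of
#' the total demand, so most sires have progeny in more than one flock-year and
#' the groups are genetically linked.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `pedigree` with columns `animal`, `sire`,
#'   `dam` (0 = unknown), `generation`, `sex` (`"M"`/`"F"`), `flock_year`
#'   (`NA` for ancestors) and, for lambs, `dam` doubles as the maternal-effect
#'   level. Parents always precede offspring in `animal` ordering.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, 101L, {
    g <- config$n_flock_years
    npg <- config$animals_per_group
    spg <- config$n_sires_per_group
    dpg <- config$n_dams_per_group

    pool_size <- max(spg, ceiling(g * spg / 2))   # shared sire pool
    n_dams_total <- g * dpg

    # generation 0 founders: parents of the sires and dams
    n0m <- max(2L, ceiling(pool_size / 2))
    n0f <- max(2L, ceiling((pool_size + n_dams_total) / 3))
    id0 <- seq_len(n0m + n0f)
    sex0 <- c(rep("M", n0m), rep("F", n0f))

    # generation 1: sire pool then dams
    n1 <- pool_size + n_dams_total
    id1 <- max(id0) + seq_len(n1)
    sire1 <- sample(id0[sex0 == "M"], n1, replace = TRUE)
    dam1 <- sample(id0[sex0 == "F"], n1, replace = TRUE)
    sex1 <- c(rep("M", pool_size), rep("F", n_dams_total))
    sire_pool <- id1[seq_len(pool_size)]
    dam_ids <- id1[pool_size + seq_len(n_dams_total)]

    # generation 2: lambs, grouped into flock-years
    n2 <- g * npg
    id2 <- max(id1) + seq_len(n2)
    lamb_sire <- integer(n2)
    lamb_dam <- integer(n2)
    lamb_fy <- character(n2)
    for (k in seq_len(g)) {
      rows <- (k - 1L) * npg + seq_len(npg)
      grp_sires <- sample(sire_pool, min(spg, pool_size))
      grp_dams <- dam_ids[(k - 1L) * dpg + seq_len(dpg)]
      # dams used as evenly as possible (1-2 lambs each)
      dam_assign <- rep(grp_dams, length.out = npg)[sample.int(npg)]
      lamb_sire[rows] <- sample(grp_sires, npg, replace = TRUE)
      lamb_dam[rows] <- dam_assign
      lamb_fy[rows] <- sprintf("FY%02d", k)
    }
    sex2 <- sample(c("M", "F"), n2, replace = TRUE)

    ped <- data.frame(
      animal = c(id0, id1, id2),
      sire = c(rep(0L, length(id0)), sire1, lamb_sire),
      dam = c(rep(0L, length(id0)), dam1, lamb_dam),
      generation = c(rep(0L, length(id0)), rep(1L, n1), rep(2L, n2)),
      sex = c(sex0, sex1, sex2),
      flock_year = c(rep(NA_character_, length(id0) + n1), lamb_fy),
      stringsAsFactors = FALSE
    )
    class(ped) <- c("pedigree", "data.frame")
    validate_pedigree(ped)
    ped
  })
}

#' Validate pedigree invariants
#'
#' Checks that parents precede offspring, that no animal is its own ancestor
#' and that unknown parents use the single sentinel 0.
#'
#' @param ped a pedigree `data.frame` with `animal`, `sire`, `dam` columns.
#' @return the pedigree, invisibly; errors if invalid.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$animal)) stop("duplicated animal ids in pedigree")
  known_s <- ped$sire != 0L
  known_d <- ped$dam != 0L
  if (any(!(ped$sire[known_s] %in% ped$animal))) stop("sire id missing from pedigree")
  if (any(!(ped$dam[known_d] %in% ped$animal))) stop("dam id missing from pedigree")
  pos <- match(ped$animal, ped$animal)
  spos <- match(ped$sire, ped$animal)
  dpos <- match(ped$dam, ped$animal)
  if (any(spos[known_s] >= pos[known_s]) || any(dpos[known_d] >= pos[known_d])) {
    stop("pedigree is not topologically ordered: a parent follows its offspring")
  }
  invisible(ped)
}

# Lamb cohort (phenotyped generation) of a simulated pedigree.
lamb_cohort <- function(ped) {
  ped[!is.na(ped$flock_year), , drop = FALSE]
}
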