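#' Pedigree numerator relationship matrix (tabular method)
#'
#' Recursive tabular construction with inbreeding: for animal i with parents
#' s, d (in topological order), `A[i, j] = (A[s, j] + A[d, j]) / 2` for j < i
#' and `A[i, i] = 1 + A[s, d] / 2`.
#'
#' @param ped a valid, topologically ordered pedigree.
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
build_A <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  spos <- match(ped$sire, ped$animal)
  dpos <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- spos[i]; d <- dpos[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[s, j] / 2
      if (!is.na(d)) row <- row + A[d, j] / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: contributions `alpha_i` based on the
#' Mendelian sampling variance `d_i`, which uses the parents' inbreeding
#' coefficients from [pedigree_inbreeding()].
#'
#' @param ped a valid pedigree.
#' @return sparse symmetric `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
build_Ainv <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  spos <- match(ped$sire, ped$animal)
  dpos <- match(ped$dam, ped$animal)
  Fi <- pedigree_inbreeding(ped)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- spos[i]; d <- dpos[i]
    dms <- 0.5
    if (!is.na(s) && !is.na(d)) {
      dms <- 0.5 - 0.25 * (Fi[s] + Fi[d])
    } else if (!is.na(s)) {
      dms <- 0.75 - 0.25 * Fi[s]
    } else if (!is.na(d)) {
      dms <- 0.75 - 0.25 * Fi[d]
    } else {
      dms <- 1
    }
    al <- 1 / dms
    add(i, i, al)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -al / 2); add(p, i, -al / 2)
        for (p2 in c(s, d)) if (!is.na(p2)) add(p, p2, al / 4)
      }
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(M)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p(1-p))` with `Z = M - 2p` and `p` the observed allele
#' frequencies (or supplied frequencies).
#'
#' @param M dosage matrix animals x SNPs (0/1/2), rownames = animal ids.
#' @param freq optional allele frequencies; default = observed column means/2.
#' @return dense symmetric matrix.
#' @export
build_G <- function(M, freq = NULL) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop("need at least 2 genotyped animals")
  p <- if (is.null(freq)) colMeans(M) / 2 else freq
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic")
  Z <- sweep(M[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Blend A and G into the single-step H matrix
#'
#' Weights the genomic matrix against the pedigree relationships of the
#' genotyped subset, `G_w = alpha G + (1 - alpha) A22`, and assembles the
#' standard single-step inverse
#' `H^-1 = A^-1 + [0 0; 0 G_w^-1 - A22^-1]` on the genotyped block. With no
#' genotyped animals `H = A` exactly.
#'
#' @param ped a valid pedigree.
#' @param G genomic matrix from [build_G()] (rownames = genotyped ids), or
#'   `NULL` for a pedigree-only analysis.
#' @param alpha blending weight on G (default 0.95).
#' @return object of class `relationship_set`: sparse `Ainv`, sparse `Hinv`
#'   (equal to `Ainv` when `G` is `NULL`), `ids`, `genotyped_ids`, `alpha`,
#'   and the dense blended block `Gw` when genotypes are present.
#' @export
blend_and_build_H <- function(ped, G = NULL, alpha = 0.95) {
  validate_pedigree(ped)
  ids <- as.character(ped$animal)
  Ainv <- build_Ainv(ped)
  if (is.null(G) || nrow(G) == 0L) {
    return(structure(list(Ainv = Ainv, Hinv = Ainv, ids = ids,
                          genotyped_ids = character(0), alpha = alpha, Gw = NULL),
                     class = "relationship_set"))
  }
  gids <- rownames(G)
  if (!all(gids %in% ids)) stop("genotyped ids must be a subset of pedigree ids")
  A <- build_A(ped)
  A22 <- A[gids, gids, drop = FALSE]
  Gw <- alpha * G + (1 - alpha) * A22
  block <- solve(Gw) - solve(A22)
  gi <- match(gids, ids)
  n <- length(ids)
  Hinv <- as(Ainv, "generalMatrix")
  Hinv[gi, gi] <- Hinv[gi, gi] + block
  Hinv <- Matrix::forceSymmetric(Matrix::drop0(Hinv))
  structure(list(Ainv = Ainv, Hinv = Hinv, ids = ids, genotyped_ids = gids,
                 alpha = alpha, Gw = Gw),
            class = "relationship_set")
}

#' Dense H matrix (for inspection at desk scale)
#'
#' Inverts the sparse `Hinv` of a [blend_and_build_H()] result. Intended for
#' small problems and tests; the REML solvers only ever use `Hinv`.
#'
#' @param rel a `relationship_set`.
#' @return dense symmetric matrix with dimnames = pedigree ids.
#' @export
build_H <- function(rel) {
  H <- as.matrix(Matrix::solve(rel$Hinv))
  dimnames(H) <- list(rel$ids, rel$ids)
  (H + t(H)) / 2
}
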