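#' Simulate SNP genotypes by Mendelian gene dropping
#'
#' Founders (animals with both parents unknown) receive two alleles per SNP
#' drawn from Hardy-Weinberg proportions at frequencies sampled uniformly from
#' `maf_range`; every other animal inherits one random allele from each known
#' parent (an unknown parent contributes a population allele at that SNP's
#' founder frequency). Dosages are the allele counts 0/1/2.
#'
#' @param ped a pedigree as from [simulate_pedigree()] (topologically ordered).
#' @param n_snps number of SNPs.
#' @param maf_range allele-frequency range within (0, 0.5].
#' @param seed optional seed; defaults to reusing the pedigree order only.
#' @return integer matrix animals x SNPs with rownames = animal ids and
#'   colnames `snp1..snpK`; attribute `"founder_freq"` holds the sampled
#'   founder allele frequencies.
#' @export
simulate_genotypes <- function(ped, n_snps, maf_range = c(0.05, 0.5), seed = NULL) {
  validate_pedigree(ped)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf_range must lie within (0, 0.5]")
  n_snps <- as.integer(n_snps)
  stopifnot(n_snps >= 1L)
  with_stage_seed(seed, 202L, {
    n <- nrow(ped)
    p <- runif(n_snps, maf_range[1], maf_range[2])
    # two allele matrices (paternal, maternal gamete), 0/1 coded
    h1 <- matrix(0L, n, n_snps)
    h2 <- matrix(0L, n, n_snps)
    idx <- match(ped$animal, ped$animal)
    spos <- match(ped$sire, ped$animal)
    dpos <- match(ped$dam, ped$animal)
    pop_allele <- function() rbinom(n_snps, 1L, p)
    for (i in seq_len(n)) {
      if (ped$sire[i] == 0L) {
        h1[i, ] <- pop_allele()
      } else {
        s <- spos[i]
        pick <- rbinom(n_snps, 1L, 0.5)
        h1[i, ] <- ifelse(pick == 1L, h1[s, ], h2[s, ])
      }
      if (ped$dam[i] == 0L) {
        h2[i, ] <- pop_allele()
      } else {
        d <- dpos[i]
        pick <- rbinom(n_snps, 1L, 0.5)
        h2[i, ] <- ifelse(pick == 1L, h1[d, ], h2[d, ])
      }
    }
    M <- h1 + h2
    dimnames(M) <- list(ped$animal, paste0("snp", seq_len(n_snps)))
    attr(M, "founder_freq") <- p
    M
  })
}
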