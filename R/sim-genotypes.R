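#' Simulate genotype dosages by Mendelian gene dropping
#'
#' Founder alleles are drawn binomially at SNP-specific minor allele
#' frequencies (uniform over \code{maf_range}); non-founders inherit one
#' allele from each parent, transmitted at random.  An individual with one
#' known and one unknown parent receives the unknown parent's allele from
#' the population frequency.  Dosages count minor alleles (0/1/2).
#'
#' @param ped a \code{fam_pedigree}
#' @param n_snps number of SNPs
#' @param maf_range minor allele frequency range, within (0, 0.5]
#' @param seed optional integer seed
#' @param missing_rate fraction of dosages set missing (NA)
#' @return samples x SNPs integer matrix with dimnames; the generative MAFs
#'   are attached as attribute \code{maf}
#' @export
simulate_genotypes <- function(ped, n_snps, maf_range = c(0.05, 0.5),
                               seed = NULL, missing_rate = 0) {
  stopifnot(inherits(ped, "fam_pedigree"))
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  fa <- attr(ped, "father_idx")
  mo <- attr(ped, "mother_idx")

  a1 <- matrix(0L, n, n_snps)   # paternal allele
  a2 <- matrix(0L, n, n_snps)   # maternal allele
  for (i in attr(ped, "topo_order")) {
    a1[i, ] <- transmit_allele(fa[i], a1, a2, maf, n_snps)
    a2[i, ] <- transmit_allele(mo[i], a1, a2, maf, n_snps)
  }
  g <- a1 + a2
  dimnames(g) <- list(ped$sample_id, sprintf("rs%06d", seq_len(n_snps)))
  if (missing_rate > 0) {
    drop <- stats::runif(length(g)) < missing_rate
    g[drop] <- NA_integer_
  }
  attr(g, "maf") <- maf
  g
}

transmit_allele <- function(parent, a1, a2, maf, n_snps) {
  if (is.na(parent)) {
    # unknown founder parent: population draw
    as.integer(stats::runif(n_snps) < maf)
  } else {
    pick <- stats::runif(n_snps) < 0.5
    ifelse(pick, a1[parent, ], a2[parent, ])
  }
}
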