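#' Probe quality-control filter
#'
#' Removes probes in the fixed order: (1) sex-chromosome probes,
#' (2) non-CpG probes, (3) SNP-assay probes, (4) probes on a supplied
#' convergence-failure list, (5) probes with detection p > 0.01 in more
#' than 5 percent of samples (both inequalities strict).  Returns the
#' filtered object together with the probe count after every stage.
#'
#' @param m a [methylation_matrix()], or a probe annotation data.frame when
#'   only counts are needed
#' @param convergence_failures character vector of probe ids that failed
#'   model convergence upstream
#' @param detection_frac optional per-probe fraction of samples failing
#'   detection (used when \code{m} is an annotation data.frame without a
#'   detection matrix)
#' @param det_p detection p-value threshold (strict \code{>}; default 0.01)
#' @param det_frac sample-fraction threshold (strict \code{>}; default 0.05)
#' @return list with \code{data} (filtered object, or kept probe ids when
#'   annotation-only) and \code{counts} (named, non-increasing stage counts)
#' @export
filter_probes <- function(m, convergence_failures = character(0),
                          detection_frac = NULL,
                          det_p = 0.01, det_frac = 0.05) {
  if (inherits(m, "methylation_matrix")) {
    ann <- m$annotation
    fail_frac <- rowMeans(m$detection > det_p)
  } else {
    ann <- as.data.frame(m)
    fail_frac <- if (is.null(detection_frac)) {
      stats::setNames(rep(0, nrow(ann)), ann$probe)
    } else detection_frac
  }
  if (is.null(names(fail_frac))) names(fail_frac) <- ann$probe

  counts <- c(total = nrow(ann))
  keep <- ann
  keep <- keep[!(keep$chr %in% c("X", "Y", "23", "24", "chrX", "chrY")), , drop = FALSE]
  counts["after_sex_chr"] <- nrow(keep)
  keep <- keep[keep$is_cpg, , drop = FALSE]
  counts["after_non_cpg"] <- nrow(keep)
  keep <- keep[!keep$is_snp_probe, , drop = FALSE]
  counts["after_snp_probes"] <- nrow(keep)
  keep <- keep[!(keep$probe %in% convergence_failures), , drop = FALSE]
  counts["after_convergence"] <- nrow(keep)
  keep <- keep[fail_frac[keep$probe] <= det_frac, , drop = FALSE]
  counts["after_detection"] <- nrow(keep)

  if (inherits(m, "methylation_matrix")) {
    idx <- match(keep$probe, rownames(m$beta))
    out <- methylation_matrix(m$beta[idx, , drop = FALSE],
                              m$detection[idx, , drop = FALSE], keep)
    list(data = out, counts = counts)
  } else {
    list(data = keep$probe, counts = counts)
  }
}

#' SNP quality-control filter
#'
#' Retains SNPs with call rate >= 0.97, minor allele frequency >= 0.05 and
#' Hardy-Weinberg exact-test p >= 0.001 (all inclusive).  The HWE test is
#' computed on founders only, since genotype frequencies among relatives do
#' not follow Hardy-Weinberg sampling.
#'
#' @param g samples x SNPs dosage matrix (0/1/2, NA = missing)
#' @param founders optional character vector of founder sample ids (or
#'   logical/integer index); default: all samples
#' @param call_rate,maf_min,hwe_min thresholds
#' @return list with \code{data} (filtered matrix) and \code{counts}
#'   (stage counts: total, after_call_rate, after_maf, after_hwe)
#' @export
filter_snps <- function(g, founders = NULL, call_rate = 0.97,
                        maf_min = 0.05, hwe_min = 0.001) {
  g <- as.matrix(g)
  counts <- c(total = ncol(g))

  cr <- colMeans(!is.na(g))
  keep <- cr >= call_rate
  counts["after_call_rate"] <- sum(keep)

  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- keep & maf >= maf_min
  counts["after_maf"] <- sum(keep)

  gf <- if (is.null(founders)) g else g[founders, , drop = FALSE]
  hwe_p <- apply(gf, 2, function(col) {
    col <- col[!is.na(col)]
    hwe_exact(sum(col == 2), sum(col == 1), sum(col == 0))
  })
  keep <- keep & hwe_p >= hwe_min
  counts["after_hwe"] <- sum(keep)

  list(data = g[, keep, drop = FALSE], counts = counts, maf = maf, hwe_p = hwe_p)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test by full enumeration of heterozygote counts
#' conditional on the allele counts (Levene-Haldane distribution): the
#' p-value is the summed probability of all genotype configurations no more
#' probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1)
#' @return p-value in (0, 1]
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)  # monomorphic: single configuration

  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_het = h | allele counts), Levene-Haldane
  logp <- lchoose(n, (nA - hets) / 2) +
    lchoose(n - (nA - hets) / 2, hets) +
    lchoose(n - (nA - hets) / 2 - hets, (na - hets) / 2) +
    hets * log(2) - lchoose(2 * n, nA)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-9)]))
}
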