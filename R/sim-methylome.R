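#' Methylation matrix container
#'
#' Holds a probes x samples beta matrix (values in [0, 1]), matching
#' detection p-values, and per-probe annotation with columns
#' \code{probe}, \code{chr}, \code{pos}, \code{gene}, \code{context},
#' \code{island}, \code{is_cpg}, \code{is_snp_probe}.
#'
#' @param beta probes x samples matrix, rownames = probe ids,
#'   colnames = sample ids
#' @param detection matrix of detection p-values, same shape as \code{beta}
#' @param annotation data.frame covering every probe
#' @return object of class \code{methylation_matrix}
#' @export
methylation_matrix <- function(beta, detection, annotation) {
  beta <- as.matrix(beta)
  detection <- as.matrix(detection)
  if (!all(dim(beta) == dim(detection))) stop("beta/detection dimensions differ")
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta values must lie in [0, 1]")
  if (is.null(rownames(beta))) stop("beta needs probe-id rownames")
  if (!all(rownames(beta) %in% annotation$probe)) {
    stop("annotation must cover every probe")
  }
  annotation <- annotation[match(rownames(beta), annotation$probe), , drop = FALSE]
  structure(list(beta = beta, detection = detection, annotation = annotation),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("<methylation_matrix> ", nrow(x$beta), " probes x ", ncol(x$beta),
      " samples\n", sep = "")
  invisible(x)
}

# Dirichlet draws (rows sum to 1)
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  out <- g / rowSums(g)
  colnames(out) <- names(alpha)
  out
}

#' Simulate array batch labels
#'
#' Assigns samples sequentially to chips of 12 positions, mirroring the
#' Sentrix chip/position layout of 450K arrays.
#' @param n number of samples
#' @param n_chips number of chips; default \code{ceiling(n / 12)}
#' @return data.frame with factors \code{chip} and \code{position}
#' @export
simulate_batch <- function(n, n_chips = NULL) {
  if (is.null(n_chips)) n_chips <- ceiling(n / 12)
  chip <- rep(seq_len(n_chips), each = 12, length.out = n)
  pos <- rep(seq_len(12), times = n_chips, length.out = n)
  data.frame(chip = factor(chip), position = factor(pos))
}

#' Simulate a methylation beta matrix with planted trait effects
#'
#' Beta values are generated on the logit scale as probe baseline +
#' polygenic component + trait effect + chip/position batch effects +
#' cell-fraction loadings + noise, then mapped through the inverse logit so
#' every value lies in (0, 1).  Planted effect sites shift the affected
#' group by \code{qlogis(beta0 + beta_diff) - qlogis(beta0)}, which
#' reproduces the configured median beta difference between trait groups.
#' Annotation marks a configurable share of probes as sex-chromosomal,
#' non-CpG or SNP-assay probes (planted effect sites are always autosomal
#' CpG probes so they survive QC), and a configurable fraction of probes
#' fails detection QC (detection p > 0.01 in more than 5 percent of samples).
#'
#' @param cfg a [sim_config()]
#' @param trait 0/1 vector (or numeric, standardized internally) driving
#'   the planted effects
#' @param A optional relationship matrix for the probe polygenic component
#' @param batch optional data.frame from [simulate_batch()]
#' @param cell_fractions optional matrix of leukocyte fractions
#' @param seed integer seed (default \code{cfg$seed})
#' @param eig optional [relationship_eigen()] of A
#' @return a [methylation_matrix()]; the batch data.frame and cell-fraction
#'   matrix used are attached as attributes \code{batch} and \code{cells}
#' @export
simulate_methylome <- function(cfg, trait, A = NULL, batch = NULL,
                               cell_fractions = NULL, seed = cfg$seed,
                               eig = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  n <- length(trait)
  P <- cfg$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(P))
  sample_ids <- if (!is.null(names(trait))) names(trait) else sprintf("S%04d", seq_len(n))

  eff <- cfg$effect_sites
  if (!is.null(eff)) {
    if (is.numeric(eff$probe)) eff$probe <- probe_ids[eff$probe]
    if (!all(eff$probe %in% probe_ids)) {
      stop("effect sites reference unknown probe ids: ",
           paste(setdiff(eff$probe, probe_ids), collapse = ", "))
    }
  }
  eff_idx <- if (is.null(eff)) integer(0) else match(eff$probe, probe_ids)

  # bimodal probe baselines on the logit scale, as on real arrays
  comp <- sample(1:3, P, replace = TRUE, prob = c(0.35, 0.3, 0.35))
  mu0 <- stats::rnorm(P, mean = c(-2.5, 0, 2.5)[comp], sd = 0.8)
  # keep planted sites at moderate baselines so a beta-scale shift is well defined
  mu0[eff_idx] <- stats::rnorm(length(eff_idx), 0, 0.4)

  logit <- matrix(mu0, P, n)

  # trait effect on the logit scale calibrated to the target beta difference
  if (length(eff_idx)) {
    grp <- if (all(trait %in% c(0, 1))) trait else as.numeric(scale(trait))
    beta0 <- stats::plogis(mu0[eff_idx])
    beta1 <- pmin(pmax(beta0 + eff$beta_diff, 1e-4), 1 - 1e-4)
    shift <- stats::qlogis(beta1) - stats::qlogis(beta0)
    logit[eff_idx, ] <- logit[eff_idx, ] + outer(shift, grp)
  }

  # polygenic + independent biological variation
  if (!is.null(A) || !is.null(eig)) {
    if (is.null(eig)) eig <- relationship_eigen(A)
    gsd <- cfg$probe_bio_sd * sqrt(cfg$probe_h2)
    Z <- matrix(stats::rnorm(n * P), n, P)
    logit <- logit + t(eig$vectors %*% (sqrt(eig$values) * Z)) * gsd
    logit <- logit + cfg$probe_bio_sd * sqrt(1 - cfg$probe_h2) *
      matrix(stats::rnorm(P * n), P, n)
  } else {
    logit <- logit + cfg$probe_bio_sd * matrix(stats::rnorm(P * n), P, n)
  }

  # chip / position batch effects
  if (is.null(batch)) batch <- simulate_batch(n, cfg$n_chips)
  nchip <- nlevels(batch$chip)
  chip_eff <- matrix(stats::rnorm(P * nchip, sd = cfg$batch_sd), P, nchip)
  pos_eff <- matrix(stats::rnorm(P * 12, sd = cfg$batch_sd / 2), P, 12)
  logit <- logit + chip_eff[, as.integer(batch$chip), drop = FALSE] +
    pos_eff[, as.integer(batch$position), drop = FALSE]

  # cell-composition loadings
  if (is.null(cell_fractions)) cell_fractions <- rdirichlet(n, cfg$cell_alpha)
  load <- matrix(stats::rnorm(P * ncol(cell_fractions), sd = cfg$cell_sd),
                 P, ncol(cell_fractions))
  logit <- logit + load %*% t(scale(cell_fractions, scale = FALSE))

  logit <- logit + cfg$probe_noise_sd * matrix(stats::rnorm(P * n), P, n)
  beta <- stats::plogis(logit)
  dimnames(beta) <- list(probe_ids, sample_ids)

  # detection p-values: clean probes tiny, failing probes > 0.01 in > 5% samples
  det <- matrix(stats::runif(P * n, 0, 0.005), P, n, dimnames = dimnames(beta))
  n_fail <- round(cfg$detection_fail_frac * P)
  fail_pool <- setdiff(seq_len(P), eff_idx)
  if (n_fail > 0 && length(fail_pool) >= n_fail) {
    fp <- sample(fail_pool, n_fail)
    for (p in fp) {
      bad <- sample.int(n, max(2L, ceiling(0.08 * n)))
      det[p, bad] <- stats::runif(length(bad), 0.011, 0.5)
    }
  }

  annotation <- simulate_probe_annotation(cfg, probe_ids, eff_idx)
  m <- methylation_matrix(beta, det, annotation)
  attr(m, "batch") <- batch
  attr(m, "cells") <- cell_fractions
  m
}

simulate_probe_annotation <- function(cfg, probe_ids, eff_idx) {
  P <- length(probe_ids)
  n_sex <- round(cfg$frac_sex_chr * P)
  n_noncpg <- round(cfg$frac_noncpg * P)
  n_snp <- max(if (cfg$frac_snp_probe > 0) 1L else 0L, round(cfg$frac_snp_probe * P))
  pool <- setdiff(seq_len(P), eff_idx)
  sex_idx <- if (n_sex) sample(pool, min(n_sex, length(pool))) else integer(0)
  pool <- setdiff(pool, sex_idx)
  noncpg_idx <- if (n_noncpg) sample(pool, min(n_noncpg, length(pool))) else integer(0)
  pool <- setdiff(pool, noncpg_idx)
  snp_idx <- if (n_snp) sample(pool, min(n_snp, length(pool))) else integer(0)

  chr <- as.character(sample(1:22, P, replace = TRUE))
  chr[sex_idx] <- sample(c("X", "Y"), length(sex_idx), replace = TRUE, prob = c(0.9, 0.1))
  data.frame(
    probe = probe_ids,
    chr = chr,
    pos = sample.int(2e8, P, replace = TRUE),
    gene = paste0("GENE", sample.int(max(20L, P %/% 10), P, replace = TRUE)),
    context = sample(c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR", "IGR"),
                     P, replace = TRUE),
    island = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                    P, replace = TRUE),
    is_cpg = !(seq_len(P) %in% noncpg_idx),
    is_snp_probe = seq_len(P) %in% snp_idx,
    stringsAsFactors = FALSE
  )
}
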