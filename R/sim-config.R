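#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults emulate the
#' study conditions the pipeline was built for: 39 extended Mexican-American
#' families totalling ~850 individuals, a binary hypertriglyceridemic-waist
#' (HTGW) phenotype with liability heritability 0.52 and prevalence 0.26,
#' a waist/triglyceride trait pair with (h2_i, h2_j, rho_G, rho_E) =
#' (0.3, 0.2, 0.07, 0.32), methylation effect sites producing 1-2
#' percentage-point median beta differences between phenotype groups, and
#' Mendelian gene-dropped genotypes.
#'
#' @param n_families number of extended families.
#' @param n_individuals target total cohort size (achieved within 10\%).
#' @param mean_children_g2 mean sibship size of the founder couple.
#' @param mean_children_g3 mean sibship size of each second-generation couple.
#' @param h2 generative narrow-sense heritability of the focal trait.
#' @param prevalence population prevalence of the binary trait.
#' @param bivariate list with \code{h2_i}, \code{h2_j}, \code{rhoG}, \code{rhoE}.
#' @param n_probes number of methylation probes.
#' @param effect_sites data.frame with columns \code{probe} (id, or index) and
#'   \code{beta_diff} (target median beta difference between trait groups);
#'   \code{NULL} for a null methylome.
#' @param probe_noise_sd residual probe noise SD on the logit scale.
#' @param probe_h2 heritability of the biological (polygenic) probe component.
#' @param probe_bio_sd SD of the biological probe component (logit scale).
#' @param batch_sd SD of chip and position batch effects (logit scale).
#' @param n_chips number of chips (12 positions each).
#' @param cell_alpha Dirichlet concentration for 5 leukocyte fractions
#'   (CD4T, CD8T, B, NK, granulocytes).
#' @param cell_sd SD of the cell-fraction loadings on probe logits.
#' @param frac_sex_chr,frac_noncpg,frac_snp_probe annotation fractions used
#'   to exercise the probe filters.
#' @param detection_fail_frac fraction of probes that fail detection QC.
#' @param n_snps number of SNPs.
#' @param maf_range minor-allele-frequency range for founder alleles.
#' @param geno_missing_rate genotype missingness rate.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_families = 39,
                       n_individuals = 850,
                       mean_children_g2 = 3.2,
                       mean_children_g3 = 3.0,
                       h2 = 0.52,
                       prevalence = 0.26,
                       bivariate = list(h2_i = 0.3, h2_j = 0.2,
                                        rhoG = 0.07, rhoE = 0.32),
                       n_probes = 2000,
                       effect_sites = NULL,
                       probe_noise_sd = 0.10,
                       probe_h2 = 0.3,
                       probe_bio_sd = 0.10,
                       batch_sd = 0.05,
                       n_chips = NULL,
                       cell_alpha = c(CD4T = 12, CD8T = 6, B = 4, NK = 3, Gran = 50),
                       cell_sd = 0.3,
                       frac_sex_chr = 11648 / 485577,
                       frac_noncpg = 2994 / 485577,
                       frac_snp_probe = 65 / 485577,
                       detection_fail_frac = 0.003,
                       n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       geno_missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              n_individuals = as.integer(n_individuals),
              mean_children_g2 = mean_children_g2,
              mean_children_g3 = mean_children_g3,
              h2 = h2, prevalence = prevalence, bivariate = bivariate,
              n_probes = as.integer(n_probes), effect_sites = effect_sites,
              probe_noise_sd = probe_noise_sd, probe_h2 = probe_h2,
              probe_bio_sd = probe_bio_sd,
              batch_sd = batch_sd, n_chips = n_chips,
              cell_alpha = cell_alpha, cell_sd = cell_sd,
              frac_sex_chr = frac_sex_chr, frac_noncpg = frac_noncpg,
              frac_snp_probe = frac_snp_probe,
              detection_fail_frac = detection_fail_frac,
              n_snps = as.integer(n_snps), maf_range = maf_range,
              geno_missing_rate = geno_missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_families < 1L) stop("configuration error: n_families must be >= 1")
  frac_in_01 <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)
  if (!frac_in_01(cfg$h2)) stop("configuration error: h2 must lie in [0,1]")
  if (!(cfg$prevalence > 0 && cfg$prevalence < 1)) {
    stop("configuration error: prevalence must lie in (0,1)")
  }
  bv <- cfg$bivariate
  if (!frac_in_01(c(bv$h2_i, bv$h2_j))) stop("configuration error: bivariate h2 in [0,1]")
  if (abs(bv$rhoG) > 1 || abs(bv$rhoE) > 1) stop("configuration error: |rho| <= 1 required")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5)) {
    stop("configuration error: maf_range must lie in (0, 0.5]")
  }
  # a three-generation family needs at least a trio
  if (cfg$n_individuals < 3L * cfg$n_families && cfg$n_individuals > 3L) {
    stop("configuration error: n_individuals too small for n_families three-generation families")
  }
  invisible(cfg)
}
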