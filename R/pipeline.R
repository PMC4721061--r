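#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort (or NULL when
#'   \code{paths} supplies real-format inputs)
#' @param paths optional named list of input files (\code{pedigree},
#'   \code{phenotypes}, \code{methylation_prefix}, \code{genotypes})
#' @param covariate_set \code{"A"}, \code{"B"} or a character vector of
#'   phenotype column shorthands (see [expand_covariates()]) used for the
#'   association scans' clinical covariates
#' @param scans character subset of \code{c("ewas", "gwas")}
#' @param fdr false-discovery-rate level for declaring scan hits
#' @param medication_mode \code{"adjust"} (medication flags as covariates),
#'   \code{"ignore"} (flags dropped) or \code{"exclude"} (medicated
#'   individuals removed)
#' @param n_pcs ancestry principal components for the GWAS covariates
#' @param seed integer master seed
#' @param outdir optional output directory for the report TSVs
#' @return object of class \code{run_config}
#' @export
run_config <- function(sim = sim_config(), paths = NULL,
                       covariate_set = "A",
                       scans = "ewas", fdr = 0.05,
                       medication_mode = c("adjust", "ignore", "exclude"),
                       n_pcs = 4, seed = sim$seed, outdir = NULL) {
  medication_mode <- match.arg(medication_mode)
  stopifnot(fdr > 0, fdr < 1, all(scans %in% c("ewas", "gwas")))
  structure(list(sim = sim, paths = paths, covariate_set = covariate_set,
                 scans = scans, fdr = fdr, medication_mode = medication_mode,
                 n_pcs = n_pcs, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Expand covariate shorthands into a design matrix
#'
#' Recognized shorthands: \code{age}, \code{age2}, \code{sex},
#' \code{age_sex}, \code{age2_sex}, \code{bmi}, \code{sbp}, \code{dbp},
#' \code{med_lipid}, \code{med_hyp}, \code{med_diab}, \code{t2d},
#' \code{obesity}; anything else must be a column of \code{pheno}.
#'
#' @param pheno phenotype data.frame (needs \code{age} and \code{sex} for
#'   the interaction shorthands)
#' @param names character vector of shorthands/column names
#' @return numeric matrix (no intercept)
#' @export
expand_covariates <- function(pheno, names) {
  sexm <- as.numeric(pheno$sex == 1)   # male indicator
  cols <- lapply(names, function(nm) {
    switch(nm,
           age = pheno$age,
           age2 = pheno$age^2,
           sex = sexm,
           age_sex = pheno$age * sexm,
           age2_sex = pheno$age^2 * sexm,
           obesity = as.numeric(pheno$bmi >= 30),
           {
             if (!nm %in% colnames(pheno)) stop("unknown covariate: ", nm)
             as.numeric(pheno[[nm]])
           })
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names
  out
}

covariate_set_names <- function(set, medication_mode = "adjust") {
  meds <- c("med_lipid", "med_hyp")
  meds_b <- c(meds, "med_diab")
  base <- c("age", "age2", "sex", "age_sex", "age2_sex")
  nm <- if (identical(set, "A")) {
    c(base, "bmi", "sbp", "dbp", meds)
  } else if (identical(set, "B")) {
    c(base, "bmi", "sbp", "dbp", meds_b)
  } else {
    set
  }
  if (medication_mode != "adjust") nm <- setdiff(nm, meds_b)
  nm
}

#' Simulate the full phenotype table for a pedigree
#'
#' Age, sex (from the pedigree), waist circumference and triglycerides
#' (a bivariate polygenic pair mapped onto clinical scales), BMI, blood
#' pressures, medication flags, T2D status (partly driven by HTGW, so
#' mediation is detectable), and fasting glucose.
#'
#' @param ped a \code{fam_pedigree}
#' @param cfg a [sim_config()]
#' @param eig [relationship_eigen()] of the pedigree's relationship matrix
#' @param seed integer seed
#' @return data.frame, one row per individual in pedigree order
#' @export
simulate_phenotypes <- function(ped, cfg, eig, seed = cfg$seed) {
  set.seed(seed)
  n <- nrow(ped)
  sex <- ped$sex
  age <- round(clamp(stats::rnorm(n, 46.75, 14.54), 18, 95), 1)

  bv <- cfg$bivariate
  yz <- simulate_bivariate(ped, NULL, bv$h2_i, bv$h2_j, bv$rhoG, bv$rhoE, eig = eig)
  waist <- ifelse(sex == 1, 100, 95) + 12 * yz[, "y_i"]
  tg <- pmax(0.3, ifelse(sex == 1, 1.6, 1.2) + 0.6 * yz[, "y_j"])

  htgw <- make_htgw(waist, tg, sex)
  zh <- as.numeric(scale(htgw))
  lt2d <- 0.45 * zh + drop(rmvn_eig(eig, s2 = 0.25)) + stats::rnorm(n, sd = sqrt(0.55))
  t2d <- simulate_binary_trait(lt2d, 0.21)
  fbg <- 5.2 + 0.9 * lt2d + stats::rnorm(n, sd = 0.5)

  data.frame(sample_id = ped$sample_id, fid = ped$fid, sex = sex, age = age,
             waist = round(waist, 1), tg = round(tg, 3),
             bmi = round(clamp(stats::rnorm(n, 31, 5.5), 16, 60), 1),
             sbp = round(clamp(stats::rnorm(n, 125, 16), 85, 220)),
             dbp = round(clamp(stats::rnorm(n, 78, 10), 45, 130)),
             med_lipid = stats::rbinom(n, 1, 0.14),
             med_hyp = stats::rbinom(n, 1, 0.24),
             med_diab = stats::rbinom(n, 1, 0.16),
             t2d = t2d, fbg = round(fbg, 2),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), HTGW construction,
#' probe (and SNP) QC filters with stage-count reports, HTGW heritability
#' with its boundary LRT, waist-triglyceride bivariate decomposition, the
#' EWAS scan (and optionally the GWAS scan with ancestry PCs), and for
#' every FDR-significant CpG site the specificity model, the
#' interactive-component model, Sobel mediation to T2D, and the forward
#' stepwise K-L ladder.  Reports are returned as data.frames and, when
#' \code{cfg$outdir} is set, written as TSV files together with a
#' structured run log.
#'
#' @param cfg a [run_config()]
#' @return object of class \code{famews_run}
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  say("famews run: seed = ", cfg$seed, ", R ", getRversion())

  ## ---- data ----
  sim <- cfg$sim
  res <- list(config = cfg)
  if (!is.null(cfg$paths)) {
    ped <- stage("load", read_pedigree(cfg$paths$pedigree))
    pheno <- stage("load", read_tsv(cfg$paths$phenotypes))
    A <- relationship_matrix(ped)
    eig <- relationship_eigen(A)
    meth <- if (!is.null(cfg$paths$methylation_prefix)) {
      stage("load", read_methylation(cfg$paths$methylation_prefix))
    }
    geno <- if (!is.null(cfg$paths$genotypes)) {
      stage("load", read_matrix_tsv(cfg$paths$genotypes))
    }
  } else {
    ped <- stage("simulate", simulate_pedigrees(sim))
    A <- relationship_matrix(ped)
    eig <- relationship_eigen(A)
    pheno <- stage("simulate", simulate_phenotypes(ped, sim, eig, seed = sim$seed + 1L))
    say("simulated ", nrow(ped), " individuals in ", length(unique(ped$fid)), " families")
  }

  ## ---- HTGW ----
  htgw <- stage("htgw", make_htgw(pheno$waist, pheno$tg, pheno$sex))
  comp <- component_indicators(pheno$waist, pheno$tg, pheno$sex)
  say("HTGW prevalence: ", sum(htgw, na.rm = TRUE), "/", length(htgw), " = ",
      round(100 * mean(htgw, na.rm = TRUE)), "%")
  pheno$htgw <- htgw

  if (is.null(cfg$paths)) {
    meth <- stage("simulate",
                  simulate_methylome(sim, stats::setNames(htgw, pheno$sample_id),
                                     eig = eig, seed = sim$seed + 2L))
    geno <- if ("gwas" %in% cfg$scans) {
      stage("simulate", simulate_genotypes(ped, sim$n_snps, sim$maf_range,
                                           seed = sim$seed + 3L))
    }
  }

  ## ---- medication handling ----
  keep <- rep(TRUE, nrow(pheno))
  if (cfg$medication_mode == "exclude") {
    keep <- pheno$med_lipid == 0 & pheno$med_hyp == 0 & pheno$med_diab == 0
    say("medication mode 'exclude': keeping ", sum(keep), " unmedicated individuals")
    ped_ids <- pheno$sample_id[keep]
    A <- A[ped_ids, ped_ids]
    eig <- relationship_eigen(A)
    pheno <- pheno[keep, , drop = FALSE]
    htgw <- htgw[keep]; comp <- comp[keep, , drop = FALSE]
    if (!is.null(meth)) {
      meth <- methylation_matrix(meth$beta[, keep, drop = FALSE],
                                 meth$detection[, keep, drop = FALSE],
                                 meth$annotation)
    }
    if (!is.null(geno)) geno <- geno[keep, , drop = FALSE]
  }
  batch <- attr(meth, "batch")
  cells <- attr(meth, "cells")
  if (!is.null(batch) && cfg$medication_mode == "exclude") {
    batch <- batch[keep, , drop = FALSE]; cells <- cells[keep, , drop = FALSE]
  }

  ## ---- heritability of HTGW ----
  Xh <- cbind(1, expand_covariates(
    pheno, covariate_set_names("A", cfg$medication_mode)))
  colnames(Xh)[1] <- "(Intercept)"
  fit_h2 <- stage("heritability",
                  fit_polygenic(htgw, Xh, kind = "liability", eig = eig))
  h2_test <- heritability_test(fit_h2)
  say(sprintf("HTGW heritability: h2 = %.3f (p = %.3g)", fit_h2$h2, h2_test$p.value))

  ## ---- bivariate waist-TG decomposition ----
  Xbv <- cbind(1, expand_covariates(
    pheno, covariate_set_names(cfg$covariate_set, cfg$medication_mode)))
  bv_fit <- stage("bivariate",
                  fit_bivariate(inverse_normal(pheno$waist), inverse_normal(pheno$tg),
                                Xbv, eig = eig))
  say(sprintf("waist-TG: rhoP = %.3f, rhoG = %.3f (p = %.3g), rhoE = %.3f (p = %.3g)",
              bv_fit$rhoP_residual, bv_fit$rhoG, bv_fit$p_rhoG,
              bv_fit$rhoE, bv_fit$p_rhoE))

  ## ---- EWAS ----
  ewas <- NULL; filter_report <- NULL; sig <- character(0)
  if ("ewas" %in% cfg$scans && !is.null(meth)) {
    pre <- stage("probe_filter", filter_probes(meth))
    mkeep <- pre$data
    markers <- t(apply(mkeep$beta, 1, inverse_normal))
    Xe <- build_batch_covariates(pheno, batch, cells, cfg$medication_mode)
    ewas <- stage("ewas", association_scan(markers, htgw, Xe, kind = "liability",
                                           eig = eig))
    # fold the per-marker convergence failures back into the stage counts
    filter_report <- filter_probes(meth, convergence_failures = ewas$failed)$counts
    say("EWAS: ", ewas$counts["converged"], "/", ewas$counts["markers"],
        " probes converged, lambda_median = ", signif(ewas$lambda_median, 4))
    sig <- ewas$table$marker[!is.na(ewas$table$q) & ewas$table$q < cfg$fdr]
    say("EWAS hits at FDR ", cfg$fdr, ": ", length(sig))
  }

  ## ---- GWAS ----
  gwas <- NULL; snp_report <- NULL
  if ("gwas" %in% cfg$scans && !is.null(geno)) {
    founders <- pheno$sample_id[attr(ped, "founder")[match(pheno$sample_id, ped$sample_id)]]
    fs <- stage("snp_filter", filter_snps(geno, founders = intersect(founders, rownames(geno))))
    snp_report <- fs$counts
    gimp <- fs$data
    gimp[is.na(gimp)] <- rep(colMeans(gimp, na.rm = TRUE),
                             each = nrow(gimp))[is.na(gimp)]
    pcs <- ancestry_pcs(gimp, min(cfg$n_pcs, ncol(gimp)))
    Xg <- cbind(expand_covariates(pheno, covariate_set_names(
      c("age", "age2", "sex", "age_sex", "age2_sex",
        "med_lipid", "med_hyp", "med_diab"), cfg$medication_mode)), pcs)
    gwas <- stage("gwas", association_scan(t(gimp), htgw, Xg, kind = "liability",
                                           eig = eig))
    say("GWAS: ", gwas$counts["converged"], "/", gwas$counts["markers"],
        " SNPs, lambda_median = ", signif(gwas$lambda_median, 4))
  }

  ## ---- follow-ups on significant sites ----
  followup <- NULL
  if (length(sig)) {
    followup <- stage("posthoc",
                      followup_sites(sig, mkeep, htgw, pheno, batch, cells,
                                     comp, eig, cfg$medication_mode))
    say("follow-up analyses on ", length(sig), " site(s) complete")
  } else if (!is.null(ewas)) {
    say("no significant sites; follow-ups skipped")
  }

  res <- c(res, list(pedigree = ped, phenotypes = pheno,
                     heritability = list(fit = fit_h2, test = h2_test),
                     bivariate = bv_fit, ewas = ewas, gwas = gwas,
                     probe_filter = filter_report, snp_filter = snp_report,
                     significant = sig, followup = followup, log = log))
  class(res) <- "famews_run"
  if (!is.null(cfg$outdir)) write_run_reports(res, cfg$outdir)
  res
}

build_batch_covariates <- function(pheno, batch, cells, medication_mode) {
  Xe <- expand_covariates(pheno, covariate_set_names(
    c("age", "age2", "sex", "age_sex", "age2_sex",
      "med_lipid", "med_hyp", "med_diab"), medication_mode))
  if (!is.null(batch)) {
    bm <- stats::model.matrix(~ chip + position, batch)[, -1, drop = FALSE]
    bm <- bm[, apply(bm, 2, stats::sd) > 0, drop = FALSE]
    Xe <- cbind(Xe, bm)
  }
  if (!is.null(cells)) {
    # fractions sum to 1: drop the last to keep the design full rank
    Xe <- cbind(Xe, cells[, -ncol(cells), drop = FALSE])
  }
  Xe
}

followup_sites <- function(sig, mkeep, htgw, pheno, batch, cells, comp, eig,
                           medication_mode) {
  Xe <- build_batch_covariates(pheno, batch, cells, medication_mode)
  Xspec <- cbind(Xe, expand_covariates(pheno, c("t2d", "obesity", "sbp", "dbp")))
  rows <- lapply(sig, function(pid) {
    z <- inverse_normal(mkeep$beta[pid, ])
    spec <- fixed_effect_test(htgw, cbind(1, Xspec, site = z), focal = "site",
                              kind = "liability", eig = eig)
    inter <- lapply(colnames(comp), function(cc) {
      fixed_effect_test(z, cbind(1, Xe, comp), focal = cc,
                        kind = "continuous", eig = eig)
    })
    med <- sobel_mediation(z, htgw, pheno$t2d, Xe,
                           kind_mediator = "liability",
                           kind_outcome = "liability", eig = eig)
    data.frame(probe = pid,
               median_diff = group_median_diff(mkeep$beta[pid, ], htgw),
               b_specific = spec$coef, p_specific = spec$p.value,
               b_both = inter[[1]]$coef, p_both = inter[[1]]$p.value,
               b_waist_only = inter[[2]]$coef, p_waist_only = inter[[2]]$p.value,
               b_tg_only = inter[[3]]$coef, p_tg_only = inter[[3]]$p.value,
               mediation = med$product, p_mediation = med$p.value,
               stringsAsFactors = FALSE)
  })
  table2 <- do.call(rbind, rows)
  zmat <- t(apply(mkeep$beta[sig, , drop = FALSE], 1, inverse_normal))
  ladder <- stepwise_kl(t(zmat), htgw, Xe, kind = "liability", eig = eig)
  list(table2 = table2, ladder = ladder)
}

#' @export
print.famews_run <- function(x, ...) {
  cat("<famews_run>\n")
  for (l in x$log) cat("  ", l, "\n", sep = "")
  invisible(x)
}

write_run_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_tsv(res$phenotypes, fp("phenotypes.tsv"))
  h <- res$heritability
  write_tsv(data.frame(trait = "htgw", h2 = h$fit$h2, se_note = "liability scale",
                       lrt = h$test$statistic, p = h$test$p.value,
                       n = h$fit$n), fp("heritability.tsv"))
  bv <- res$bivariate
  write_tsv(data.frame(trait_i = "waist", trait_j = "tg",
                       rhoP = bv$rhoP, rhoP_residual = bv$rhoP_residual,
                       rhoG = bv$rhoG, rhoE = bv$rhoE,
                       p_G = bv$p_rhoG, p_E = bv$p_rhoE),
            fp("bivariate.tsv"))
  if (!is.null(res$ewas)) {
    write_tsv(res$ewas$table, fp("ewas.tsv"))
    write_tsv(data.frame(stage = names(res$probe_filter),
                         probes = as.integer(res$probe_filter)),
              fp("probe_filter.tsv"))
    ann <- NULL
  }
  if (!is.null(res$gwas)) {
    write_tsv(res$gwas$table, fp("gwas.tsv"))
    write_tsv(data.frame(stage = names(res$snp_filter),
                         snps = as.integer(res$snp_filter)), fp("snp_filter.tsv"))
  }
  if (!is.null(res$followup)) {
    write_tsv(res$followup$table2, fp("table2_followup.tsv"))
    write_tsv(as.data.frame(res$followup$ladder), fp("table3_kl_ladder.tsv"))
  }
  writeLines(res$log, fp("run.log"))
  invisible(outdir)
}
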