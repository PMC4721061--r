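test_that("pedigree simulation hits the configured family and cohort sizes", {
  ped <- study_eig()$ped
  s <- ped_summary(ped)
  expect_equal(unname(s["families"]), 39L)
  expect_gte(unname(s["n"]), 765L)
  expect_lte(unname(s["n"]), 935L)
  # three generations present: someone has a non-founder parent
  fa <- attr(ped, "father_idx")
  expect_true(any(!is.na(fa) & !attr(ped, "founder")[ifelse(is.na(fa), 1L, fa)]))

  trio <- simulate_pedigrees(sim_config(seed = 2, n_families = 1, n_individuals = 3))
  expect_equal(unname(ped_summary(trio)), c(3L, 2L, 1L))

  p1 <- simulate_pedigrees(sim_config(seed = 5, n_families = 6, n_individuals = 120))
  p2 <- simulate_pedigrees(sim_config(seed = 5, n_families = 6, n_individuals = 120))
  expect_identical(p1, p2)
  expect_error(sim_config(n_families = 10, n_individuals = 12), "configuration")
})

test_that("polygenic trait generator has the stated covariance structure", {
  ped <- founder_ped(400)
  eig <- relationship_eigen(relationship_matrix(ped))
  # founders only, h2 = 1: trait is iid standard normal
  y <- simulate_polygenic_trait(ped, NULL, 1, seed = 3, eig = eig)
  expect_lt(abs(mean(y)), 0.2)
  expect_lt(abs(sd(y) - 1), 0.15)
  # determinism
  y2 <- simulate_polygenic_trait(ped, NULL, 1, seed = 3, eig = eig)
  expect_identical(y, y2)
  # h2 = 0: no family resemblance even among sibs
  sib <- ped_from_text("
F1 f 0 0 1
F1 m 0 0 2
F1 a f m 1
F1 b f m 2
")
  eigs <- relationship_eigen(relationship_matrix(sib))
  ys <- replicate(400, {
    y <- simulate_polygenic_trait(sib, NULL, 0, eig = eigs)
    y[3:4]
  })
  expect_lt(abs(cor(ys[1, ], ys[2, ])), 0.15)
})

test_that("binary trait threshold controls prevalence exactly", {
  se <- study_eig()
  l <- simulate_polygenic_trait(se$ped, NULL, 0.52, seed = 4, eig = se$eig)
  y <- simulate_binary_trait(l, 0.26)
  n <- length(l)
  expect_lte(abs(sum(y) - round(0.26 * n)), 1)
  y5 <- simulate_binary_trait(l, 0.5)
  expect_lte(abs(sum(y5) - n / 2), 1)
  expect_true(all(l[y5 == 1] > median(l) - 1e-9))
  expect_identical(y, simulate_binary_trait(l, 0.26))
  expect_error(simulate_binary_trait(l, 0), "prevalence")
})

test_that("bivariate generator reproduces the phenotypic-correlation identity", {
  se <- study_eig()
  # null: independent traits
  y0 <- simulate_bivariate(se$ped, NULL, 0.3, 0.2, 0, 0, seed = 5, eig = se$eig)
  expect_lt(abs(cor(y0[, 1], y0[, 2])), 0.1)
  # fully genetic limit
  y1 <- simulate_bivariate(se$ped, NULL, 1, 1, 0.6, 0, seed = 6, eig = se$eig)
  expect_lt(abs(cor(y1[, 1], y1[, 2]) - 0.6), 0.1)
  # study parameters against the closed form
  rhoP <- 0.07 * sqrt(0.3 * 0.2) + 0.32 * sqrt(0.7 * 0.8)
  r <- replicate(10, {
    yz <- simulate_bivariate(se$ped, NULL, 0.3, 0.2, 0.07, 0.32, eig = se$eig)
    cor(yz[, 1], yz[, 2])
  })
  expect_lt(abs(mean(r) - rhoP), 0.05)
  expect_error(simulate_bivariate(se$ped, NULL, 0.3, 0.2, 1.4, 0, eig = se$eig),
               "configuration")
})

test_that("methylome simulation plants calibrated effects and valid QC structure", {
  se <- small_eig()
  n <- nrow(se$ped)
  cfg <- sim_config(seed = 9, n_probes = 120, detection_fail_frac = 0.05,
                    effect_sites = data.frame(probe = c(5, 10),
                                              beta_diff = c(0.016, -0.012)))
  y <- rep_len(c(0L, 1L), n)
  names(y) <- se$ped$sample_id
  m <- simulate_methylome(cfg, y, eig = se$eig, seed = 10)
  expect_true(all(m$beta >= 0 & m$beta <= 1))
  expect_equal(dim(m$beta), c(120L, n))
  expect_setequal(m$annotation$probe, rownames(m$beta))
  # planted sites reproduce the configured median differences on average
  # (a single finite-sample group median is noisy; average 8 realizations)
  d <- rowMeans(sapply(1:25, function(s) {
    mm <- simulate_methylome(cfg, y, eig = se$eig, seed = s)
    c(group_median_diff(mm$beta["cg00000005", ], y),
      group_median_diff(mm$beta["cg00000010", ], y))
  }))
  expect_lt(abs(d[1] - 0.016), 0.006)
  expect_lt(abs(d[2] + 0.012), 0.006)
  # detection failures present at roughly the configured rate
  fail <- rowMeans(m$detection > 0.01) > 0.05
  expect_equal(sum(fail), 6)
  expect_identical(m$beta, simulate_methylome(cfg, y, eig = se$eig, seed = 10)$beta)
})

test_that("gene dropping yields Mendelian, HWE-consistent genotypes", {
  g <- simulate_genotypes(founder_ped(3000), 1, maf_range = c(0.5, 0.5), seed = 1)
  freq <- table(factor(g[, 1], levels = 0:2)) / 3000
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.03)

  ped <- study_eig()$ped
  g <- simulate_genotypes(ped, 300, seed = 2)
  fa <- attr(ped, "father_idx")
  kids <- which(!is.na(fa))
  for (i in kids[1:50]) {
    expect_false(any(abs(g[i, ] - g[fa[i], ]) == 2))
  }

  # full-sib dosage correlation across SNPs ~ A_ij = 0.5
  sibs <- ped_from_text("
F1 f 0 0 1
F1 m 0 0 2
F1 a f m 1
F1 b f m 2
")
  gs <- simulate_genotypes(sibs, 4000, maf_range = c(0.2, 0.4), seed = 3)
  expect_lt(abs(cor(gs["a", ], gs["b", ]) - 0.5), 0.08)
  expect_identical(gs, simulate_genotypes(sibs, 4000, maf_range = c(0.2, 0.4), seed = 3))
})

test_that("simulated data round-trips through the writers and readers", {
  se <- small_eig()
  cfg <- sim_config(seed = 13, n_probes = 25)
  y <- simulate_binary_trait(
    simulate_polygenic_trait(se$ped, NULL, 0.5, seed = 14, eig = se$eig), 0.26)
  m <- simulate_methylome(cfg, y, eig = se$eig, seed = 15)
  pre <- withr::local_tempfile()
  write_methylation(m, pre)
  m2 <- read_methylation(pre)
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
  expect_equal(m2$annotation, m$annotation)

  g <- simulate_genotypes(se$ped, 10, seed = 16)
  f <- withr::local_tempfile()
  write_matrix_tsv(g, f)
  expect_equal(unname(read_matrix_tsv(f)), unname(g * 1.0), ignore_attr = TRUE)

  fc <- withr::local_tempfile()
  write_sim_config(cfg, fc)
  expect_true(any(grepl("n_probes=25", readLines(fc))))
})
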