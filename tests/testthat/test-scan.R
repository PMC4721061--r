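test_that("HTGW definition applies inclusive, sex-specific thresholds", {
  # male at both boundaries; female below both; male high waist only
  h <- make_htgw(waist = c(90, 80, 120), tg = c(2.0, 1.0, 1.0), sex = c(1, 2, 1))
  expect_equal(as.integer(h), c(1L, 0L, 0L))
  # female boundaries
  expect_equal(as.integer(make_htgw(85, 1.5, 2)), 1L)
  expect_equal(as.integer(make_htgw(84.9, 1.5, 2)), 0L)
  # missing components propagate and are counted
  hm <- make_htgw(c(95, NA), c(2.5, 1.0), c(1, 1))
  expect_true(is.na(hm[2]))
  expect_equal(attr(hm, "n_missing"), 1L)
})

test_that("component indicators are mutually exclusive and exhaustive", {
  waist <- c(95, 95, 70, 70)
  tg <- c(2.5, 1.0, 2.5, 1.0)
  ci <- component_indicators(waist, tg, sex = rep(1, 4))
  expect_equal(unname(ci[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(ci[2, ]), c(0L, 1L, 0L))
  expect_equal(unname(ci[3, ]), c(0L, 0L, 1L))
  expect_equal(unname(ci[4, ]), c(0L, 0L, 0L))
  expect_true(all(rowSums(ci) <= 1))
})

test_that("inverse normal transform matches quantile arithmetic and is rank-based", {
  z <- inverse_normal(c(10, 20, 30))
  expect_equal(z, qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  x <- rexp(200)
  expect_equal(inverse_normal(x), inverse_normal(log(x)))
  big <- inverse_normal(rnorm(850))
  expect_lt(abs(mean(big)), 1e-10)
  expect_lt(abs(sd(big) - 1), 0.05)
  expect_error(inverse_normal(rep(1, 10)), "constant")
  expect_error(inverse_normal(c(1, 2)), "3 non-missing")
})

test_that("probe filter applies the staged exclusions with strict detection rules", {
  ann <- data.frame(probe = paste0("p", 1:10),
                    chr = c("X", "1", "2", "Y", "3", "4", "5", "6", "7", "8"),
                    is_cpg = c(TRUE, FALSE, rep(TRUE, 8)),
                    is_snp_probe = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
  # p7 fails detection in exactly 5% (retained), p8 in 6% (removed)
  frac <- setNames(c(rep(0, 6), 0.05, 0.06, 0, 0), ann$probe)
  out <- filter_probes(ann, convergence_failures = "p6", detection_frac = frac)
  expect_equal(unname(out$counts),
               c(10L, 8L, 7L, 6L, 5L, 4L))
  expect_setequal(out$data, c("p3", "p7", "p9", "p10"))
  expect_true(all(diff(out$counts) <= 0))

  # no flagged annotation: output equals input
  clean <- data.frame(probe = c("a", "b"), chr = c("1", "2"),
                      is_cpg = TRUE, is_snp_probe = FALSE)
  expect_equal(unname(filter_probes(clean)$counts), rep(2L, 6))
})

test_that("probe filter counts ignore sample order", {
  se <- small_eig()
  cfg <- sim_config(seed = 3, n_probes = 150, detection_fail_frac = 0.04)
  y <- rep_len(c(0L, 1L), nrow(se$ped))
  m <- simulate_methylome(cfg, y, seed = 4)
  c1 <- filter_probes(m)$counts
  perm <- sample(ncol(m$beta))
  m2 <- methylation_matrix(m$beta[, perm], m$detection[, perm], m$annotation)
  expect_identical(filter_probes(m2)$counts, c1)
})

test_that("SNP filter enforces call rate, MAF and founder HWE thresholds", {
  n <- 200
  set.seed(9)
  make_snp <- function(p) rbinom(n, 2, p)
  g <- cbind(maf04 = c(rep(1L, 16), rep(0L, n - 16)),   # MAF exactly 0.04
             maf05 = c(rep(1L, 20), rep(0L, n - 20)),   # MAF exactly 0.05
             mono = rep(0L, n),
             good = make_snp(0.3),
             lowcall = make_snp(0.3),
             hwe_bad = c(rep(2L, 5), rep(1L, 90), rep(0L, 5), make_snp(0.5)[1:100]))
  g[sample(n, 10), "lowcall"] <- NA
  rownames(g) <- paste0("s", 1:n)
  out <- filter_snps(g, founders = paste0("s", 1:100))
  expect_false("maf04" %in% colnames(out$data))
  expect_false("mono" %in% colnames(out$data))
  expect_false("lowcall" %in% colnames(out$data))   # call rate 0.95 < 0.97
  expect_false("hwe_bad" %in% colnames(out$data))   # (5,90,5) in founders
  expect_true(all(c("maf05", "good") %in% colnames(out$data)))
  expect_true(all(diff(out$counts) <= 0))
})

test_that("HWE exact test matches enumeration and its symmetries", {
  expect_equal(hwe_exact(25, 50, 25), 1)
  expect_lt(hwe_exact(0, 100, 0), 1e-6)
  expect_equal(hwe_exact(3, 17, 40), hwe_exact(40, 17, 3))
  expect_equal(hwe_exact(10, 0, 0), 1)   # monomorphic

  # full-enumeration oracle with plain factorials on small counts
  hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
    pr <- sapply(hets, function(h) {
      nAA_h <- (nA - h) / 2
      naa_h <- n - nAA_h - h
      factorial(n) / (factorial(nAA_h) * factorial(h) * factorial(naa_h)) *
        2^h * factorial(nA) * factorial(2 * n - nA) / factorial(2 * n)
    })
    sum(pr[pr <= pr[hets == nAa] * (1 + 1e-9)])
  }
  for (cnt in list(c(5, 10, 15), c(2, 2, 2), c(8, 1, 3), c(0, 5, 5))) {
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("genomic inflation factor is the median chi-square ratio", {
  med <- qchisq(0.5, 1)
  expect_equal(genomic_inflation(rep(med, 7)), 1)
  x <- rexp(101)
  expect_equal(genomic_inflation(2 * x), 2 * genomic_inflation(x))
  set.seed(12)
  expect_lt(abs(genomic_inflation(rchisq(1e5, 1)) - 1), 0.01)
  expect_error(genomic_inflation(numeric(0)), "at least one")
})

test_that("inflation correction deflates only when lambda exceeds 1", {
  p <- c(0.001, 0.05, 0.5, 1)
  expect_identical(correct_inflation(p, 1), p)
  expect_identical(correct_inflation(p, 0.6152), p)
  expect_equal(correct_inflation(0.05, 2),
               pchisq(qchisq(0.05, 1, lower.tail = FALSE) / 2, 1,
                      lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(correct_inflation(0.05, 2), 0.1659, tolerance = 1e-3)
})

test_that("BH q-values reproduce step-up arithmetic and preserve order", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # manual step-up oracle
  m <- length(p)
  o <- order(p)
  qo <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(q[o], pmin(qo, 1))
})

test_that("liability coefficients transform to the printed odds ratios", {
  expect_equal(round(liability_or(0.65), 2), 3.16)
  expect_equal(liability_or(0), 1)
  res <- liability_or(0.65, ci = c(0.39, 0.90))
  expect_equal(round(res$ci, 2), c(2.00, 4.93))
})

test_that("ancestry PCs separate divergent founder populations", {
  set.seed(14)
  n <- 120; nsnp <- 300
  maf1 <- runif(nsnp, 0.05, 0.5)
  maf2 <- pmin(0.95, pmax(0.02, maf1 + sample(c(-1, 1), nsnp, TRUE) * 0.25))
  g <- rbind(sapply(maf1, function(p) rbinom(n / 2, 2, p)),
             sapply(maf2, function(p) rbinom(n / 2, 2, p)))
  rownames(g) <- paste0("s", 1:n)
  pcs <- ancestry_pcs(g, 4)
  grp <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)
  expect_lt(max(abs(crossprod(pcs[, 1], pcs[, 2]))) /
              (sqrt(sum(pcs[, 1]^2)) * sqrt(sum(pcs[, 2]^2))), 1e-8)
  expect_equal(ncol(ancestry_pcs(g, 0)), 0L)
  expect_error(ancestry_pcs(g[1:5, 1:10], 8), "rank")
})

test_that("scan on unrelated individuals matches the plain regression LRT", {
  set.seed(15)
  n <- 120
  A <- diag(n); dimnames(A) <- list(paste0("s", 1:n), paste0("s", 1:n))
  y <- rnorm(n)
  markers <- matrix(rnorm(10 * n), 10, n,
                    dimnames = list(paste0("m", 1:10), rownames(A)))
  sc <- association_scan(markers, y, A = A, lambda_correct = "off")
  p_lm <- apply(markers, 1, function(m) {
    lr <- 2 * (as.numeric(logLik(lm(y ~ m))) - as.numeric(logLik(lm(y ~ 1))))
    pchisq(lr, 1, lower.tail = FALSE)
  })
  expect_equal(unname(sc$table$p), unname(p_lm), tolerance = 1e-4)
})

test_that("empty scans return a valid result structure", {
  sc <- association_scan(matrix(0, 0, 10), rnorm(10), A = diag(10))
  expect_s3_class(sc, "scan_result")
  expect_equal(nrow(sc$table), 0L)
  expect_true(is.na(sc$lambda_median))
})

test_that("a planted probe dominates a null scan at study scale", {
  se <- study_eig()
  cfg <- sim_config(seed = 21, n_probes = 300, detection_fail_frac = 0,
                    effect_sites = data.frame(probe = 150, beta_diff = 0.016))
  top1 <- 0; qhit <- 0; nrep <- 10
  for (r in seq_len(nrep)) {
    l <- simulate_polygenic_trait(se$ped, NULL, 0.52, seed = 300 + r, eig = se$eig)
    y <- simulate_binary_trait(l, 0.26)
    m <- simulate_methylome(cfg, y, eig = se$eig, seed = 400 + r)
    sc <- association_scan(t(apply(m$beta, 1, inverse_normal)), y,
                           kind = "liability", eig = se$eig)
    i <- which(sc$table$marker == "cg00000150")
    top1 <- top1 + (which.min(sc$table$p) == i)
    qhit <- qhit + (sc$table$q[i] < 0.05)
  }
  expect_gte(top1 / nrep, 0.9)
  expect_gte(qhit / nrep, 0.8)
})
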