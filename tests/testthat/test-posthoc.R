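test_that("Sobel arithmetic matches the delta-method formula and its symmetry", {
  s <- sobel_parameter(0.5, 0.1, 0.4, 0.1)
  expect_equal(s$product, 0.20)
  expect_equal(s$se, 0.0640, tolerance = 1e-3)
  expect_equal(s$z, 3.12, tolerance = 1e-2)
  # exchanging the two paths leaves z unchanged
  s2 <- sobel_parameter(0.4, 0.1, 0.5, 0.1)
  expect_equal(s2$z, s$z)
  # a null first path gives a zero product and p = 1-ish behaviour
  s0 <- sobel_parameter(0, 0.1, 0.4, 0.1)
  expect_equal(s0$product, 0)
  expect_equal(s0$z, 0)
  expect_equal(s0$p.value, 1)
})

test_that("mediation is detected when the pathway is real", {
  se <- small_eig()
  n <- nrow(se$ped)
  hits <- sapply(1:15, function(r) {
    set.seed(800 + r)
    site <- rnorm(n)
    lmed <- 0.45 * site + simulate_polygenic_trait(se$ped, NULL, 0.4, eig = se$eig)
    med <- simulate_binary_trait(lmed, 0.3)
    out <- simulate_binary_trait(0.8 * scale(med)[, 1] + rnorm(n), 0.25)
    sobel_mediation(site, med, out, kind_mediator = "liability",
                    kind_outcome = "liability", eig = se$eig)$p.value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("K-L R-squared reduces to OLS R-squared in the Gaussian limit", {
  expect_equal(kl_r2(-100, -100, 50), 0)
  set.seed(31)
  n <- 90
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  full <- lm(y ~ x)
  null <- lm(y ~ 1)
  r2 <- kl_r2(as.numeric(logLik(full)), as.numeric(logLik(null)), n)
  expect_equal(r2, summary(full)$r.squared, tolerance = 1e-8)
  expect_error(kl_r2(-105, -100, 50), "numeric error")
})

test_that("R-squared grows when a truly associated predictor is added", {
  se <- study_eig()
  n <- nrow(se$ped)
  set.seed(32)
  x <- rnorm(n)
  X0 <- cbind(`(Intercept)` = rep(1, n))
  y <- simulate_polygenic_trait(se$ped, NULL, 0.3, X = cbind(x), b = 0.3,
                                seed = 33, eig = se$eig)
  f0 <- fit_polygenic(y, X0, eig = se$eig)
  f1 <- fit_polygenic(y, cbind(X0, x = x), eig = se$eig)
  expect_gt(kl_r2(f1, f0, n), 0)
})

test_that("ladder arithmetic: increments and total match the R-squared sequence", {
  mc <- model_comparison(c("Base", "Base+s1", "Base+s1+s2", "Base+s1+s2+s3"),
                         r2 = c(0.1015, 0.1284, 0.1728, 0.1967))
  expect_equal(mc$delta_r2[-1], c(0.0269, 0.0444, 0.0239))
  expect_equal(attr(mc, "total_added"), 0.0952)
  expect_equal(sum(mc$delta_r2[-1]), attr(mc, "total_added"))
  expect_error(model_comparison("m", 1.2), "R2")
})

test_that("forward-stepwise ladder flags real sites and ignores constants", {
  se <- small_eig()
  n <- nrow(se$ped)
  set.seed(41)
  sites <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("sA", "sB", "sC")))
  y <- simulate_polygenic_trait(se$ped, NULL, 0.3, X = sites,
                                b = c(0.35, 0.3, 0.25), seed = 42, eig = se$eig)
  mc <- stepwise_kl(sites, y, eig = se$eig)
  expect_equal(nrow(mc), 4L)
  expect_true(all(mc$delta_r2[-1] > 0))
  expect_true(all(mc$p[-1] < 0.05))
  expect_equal(sum(mc$delta_r2[-1]), attr(mc, "total_added"), tolerance = 1e-12)

  const <- cbind(sites[, 1, drop = FALSE], flat = rep(2, n))
  mc2 <- stepwise_kl(const, y, eig = se$eig)
  expect_equal(mc2$delta_r2[3], 0)
})

test_that("adjusting for comorbidities shrinks a confounded site coefficient", {
  se <- small_eig()
  n <- nrow(se$ped)
  shrink <- sapply(1:12, function(r) {
    set.seed(900 + r)
    conf <- rnorm(n)                       # comorbidity (e.g. blood pressure)
    site <- 0.6 * conf + rnorm(n)          # methylation tracks the comorbidity
    y <- 0.5 * conf + 0.1 * site +
      simulate_polygenic_trait(se$ped, NULL, 0.3, eig = se$eig)
    b0 <- fixed_effect_test(y, cbind(1, site = site), focal = "site",
                            eig = se$eig)$coef
    b1 <- fixed_effect_test(y, cbind(1, conf = conf, site = site),
                            focal = "site", eig = se$eig)$coef
    abs(b1) - abs(b0)
  })
  expect_lt(mean(shrink), 0)
})
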