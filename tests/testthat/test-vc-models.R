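test_that("with unrelated individuals the fit collapses to the OLS likelihood", {
  set.seed(101)
  n <- 80
  ped <- founder_ped(n)
  A <- relationship_matrix(ped)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  fit <- fit_polygenic(y, X, A)
  ols <- lm(y ~ X - 1)
  expect_lt(abs(fit$logL - as.numeric(logLik(ols))), 1e-6)
  expect_lt(fit$h2, 0.05)
  expect_equal(unname(fit$coef), unname(coef(ols)), tolerance = 1e-4)

  # fixed-effect LRT agrees with the Gaussian likelihood-ratio test
  fe <- fixed_effect_test(y, X, A, focal = "x")
  ols0 <- lm(y ~ 1)
  lr <- 2 * (as.numeric(logLik(ols)) - as.numeric(logLik(ols0)))
  expect_lt(abs(fe$p.value - pchisq(lr, 1, lower.tail = FALSE)), 1e-4)
})

test_that("eigen-basis likelihood equals dense evaluation", {
  se <- small_eig()
  sub <- 1:150
  ids <- se$ped$sample_id[sub]
  A <- relationship_matrix(se$ped)[ids, ids]
  eig <- relationship_eigen(A)
  y <- simulate_polygenic_trait(NULL, NULL, 0.5, seed = 21, eig = eig)
  X <- cbind(1, rnorm(150))
  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% y); Xs <- Ut %*% X
  for (h2 in c(0, 0.25, 0.6, 0.9)) {
    expect_lt(abs(famews:::vc_profile_loglik(h2, ys, Xs, eig$values) -
                    dense_vc_loglik(h2, y, X, A)), 1e-8)
  }
})

test_that("boundary LRT uses the half-half chi-square mixture", {
  expect_equal(vc_mixture_p(0), 0.5)
  expect_equal(vc_mixture_p(2.706), 0.05, tolerance = 1e-3)
  se <- small_eig()
  y <- simulate_polygenic_trait(se$ped, NULL, 0.6, seed = 31, eig = se$eig)
  fit <- fit_polygenic(y, eig = se$eig)
  ht <- heritability_test(fit)
  expect_gte(ht$statistic, 0)
  expect_equal(ht$statistic, max(0, 2 * (fit$logL - ht$logL_null)))
  expect_lt(ht$p.value, 0.05)
})

test_that("estimates are invariant to affine rescaling of the trait", {
  se <- small_eig()
  set.seed(41)
  X <- cbind(`(Intercept)` = 1, x = rnorm(220))
  y <- simulate_polygenic_trait(se$ped, NULL, 0.4, X = X, b = c(0, 0.3),
                                seed = 42, eig = se$eig)
  f1 <- fit_polygenic(y, X, eig = se$eig)
  f2 <- fit_polygenic(3 * y + 5, X, eig = se$eig)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-4)
  expect_equal(unname(f2$coef["x"]), unname(3 * f1$coef["x"]), tolerance = 1e-4)
})

test_that("degenerate and ill-posed inputs are flagged, not crashed", {
  y2 <- c(0.3, -1.2)
  f <- fit_polygenic(y2, A = diag(2))
  expect_false(f$converged)
  expect_gt(f$sigma2_e, 0)

  set.seed(51)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_polygenic(rnorm(20), X, diag(20)), "dup")

  fe <- fixed_effect_test(rnorm(20), cbind(1, z = rep(0, 20)), diag(20), focal = "z")
  expect_identical(fe$coef, 0)
  expect_identical(fe$p.value, 1)
})

test_that("liability fits recover threshold, prevalence and planted effects", {
  se <- study_eig()
  l <- simulate_polygenic_trait(se$ped, NULL, 0.52, seed = 61, eig = se$eig)
  y <- simulate_binary_trait(l, 0.26)
  fit <- fit_polygenic(y, kind = "liability", eig = se$eig)
  expect_lt(abs(fit$prevalence - 0.26), 0.02)
  expect_lt(abs(fit$threshold - qnorm(0.74)), 0.06)
  expect_gte(fit$h2, 0)
  expect_lte(fit$h2, 1)

  h2s <- sapply(1:10, function(r) {
    l <- simulate_polygenic_trait(se$ped, NULL, 0.52, seed = 600 + r, eig = se$eig)
    fit_polygenic(simulate_binary_trait(l, 0.26), kind = "liability", eig = se$eig)$h2
  })
  expect_lt(abs(mean(h2s) - 0.52), 0.1)
})

test_that("a planted fixed effect of 0.5 is detected at study scale", {
  se <- study_eig()
  n <- nrow(se$ped)
  hits <- sapply(1:20, function(r) {
    set.seed(700 + r)
    x <- rnorm(n)
    X <- cbind(`(Intercept)` = 1, x = x)
    y <- simulate_polygenic_trait(se$ped, NULL, 0.4, X = X, b = c(0, 0.5),
                                  eig = se$eig)
    fixed_effect_test(y, X, focal = "x", eig = se$eig)$p.value < 0.001
  })
  expect_gte(mean(hits), 0.95)
})
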