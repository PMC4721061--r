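#' Polygenic variance-component model
#'
#' Fits \code{y ~ MVN(X b, sigma2_g * A + sigma2_e * I)} by maximum
#' likelihood.  The relationship matrix is eigendecomposed once
#' (\code{A = U D U'}), the model is rotated into the eigenbasis, and for a
#' given heritability the fixed effects and the total variance are profiled
#' out by generalized least squares, leaving a one-dimensional profile
#' likelihood in \code{h2 = sigma2_g / (sigma2_g + sigma2_e)} that is
#' maximized over a coarse grid followed by golden-section refinement
#' (boundary-safe, reproducible; tolerance 1e-8 on the log-likelihood).
#' ML (not REML) is used throughout so likelihood-ratio tests between models
#' with different fixed effects are coherent.
#'
#' For \code{kind = "liability"} the 0/1 trait is fitted on the observed
#' scale with the same machinery and the estimates are mapped to the latent
#' liability scale: with prevalence K and threshold \code{t = qnorm(1 - K)},
#' \code{h2_liability = h2_observed * K(1-K) / dnorm(t)^2} (the classical
#' threshold-model transformation) and coefficients are scaled by
#' \code{1 / dnorm(t)}.  The reported log-likelihood (used by all LRTs) is
#' the observed-scale one; the LRT calibration is checked by simulation in
#' the package tests.
#'
#' @param y trait vector (0/1 for \code{kind = "liability"})
#' @param X covariate matrix including the intercept; default intercept-only
#' @param A additive relationship matrix (ignored when \code{eig} given)
#' @param kind \code{"continuous"} or \code{"liability"}
#' @param eig optional [relationship_eigen()] of A, reused across fits
#' @return object of class \code{vc_fit} with elements \code{sigma2_g},
#'   \code{sigma2_e}, \code{h2}, \code{coef}, \code{se}, \code{logL},
#'   \code{n}, \code{converged}, \code{kind}, and for liability fits
#'   \code{prevalence}, \code{threshold} and the observed-scale \code{h2_obs}.
#' @export
fit_polygenic <- function(y, X = NULL, A = NULL,
                          kind = c("continuous", "liability"), eig = NULL) {
  kind <- match.arg(kind)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) stop("y and X are not conformable")
  check_full_rank(X)
  if (is.null(eig)) {
    if (is.null(A)) stop("either A or eig must be supplied")
    if (any(dim(A) != n)) stop("A is not conformable with y")
    eig <- relationship_eigen(A)
  }

  if (kind == "liability") {
    if (!all(y %in% c(0, 1))) stop("liability trait must be coded 0/1")
    if (length(unique(y)) < 2L) stop("liability trait needs both classes present")
    K <- mean(y)
    thr <- stats::qnorm(1 - K)
    phi <- stats::dnorm(thr)
    obs <- polygenic_ml(y, X, eig)
    fac <- K * (1 - K) / phi^2
    h2l <- min(1, max(0, obs$h2 * fac))
    out <- list(sigma2_g = h2l, sigma2_e = 1 - h2l, h2 = h2l,
                coef = obs$coef / phi, se = obs$se / phi,
                logL = obs$logL, n = n, converged = obs$converged,
                kind = kind, prevalence = K, threshold = thr,
                h2_obs = obs$h2, sigma2p_obs = obs$sigma2p)
  } else {
    obs <- polygenic_ml(y, X, eig)
    out <- list(sigma2_g = obs$h2 * obs$sigma2p,
                sigma2_e = (1 - obs$h2) * obs$sigma2p,
                h2 = obs$h2, coef = obs$coef, se = obs$se,
                logL = obs$logL, n = n, converged = obs$converged,
                kind = kind, prevalence = NA_real_, threshold = NA_real_)
  }
  out$eig <- eig
  out$X <- X
  out$y <- y
  class(out) <- "vc_fit"
  out
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# profile log-likelihood in h2 after rotating into the eigenbasis of A
vc_profile_loglik <- function(h2, ys, Xs, d) {
  n <- length(ys)
  w <- pmax(h2 * d + (1 - h2), 1e-12)
  sw <- sqrt(w)
  fit <- stats::.lm.fit(Xs / sw, ys / sw)
  rss <- sum(fit$residuals^2)
  s2 <- rss / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
}

# ML fit on the observed scale; h2 maximized over [0, 0.9999]
polygenic_ml <- function(y, X, eig, h2_fixed = NULL) {
  n <- length(y)
  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% y)
  Xs <- Ut %*% X
  d <- eig$values

  if (!is.null(h2_fixed)) {
    h2 <- h2_fixed
    converged <- TRUE
  } else {
    grid <- c(seq(0, 0.95, by = 0.05), 0.9999)
    ll <- vapply(grid, vc_profile_loglik, numeric(1), ys = ys, Xs = Xs, d = d)
    best <- which.max(ll)
    lo <- grid[max(1L, best - 1L)]
    hi <- grid[min(length(grid), best + 1L)]
    opt <- stats::optimize(vc_profile_loglik, c(lo, hi), ys = ys, Xs = Xs, d = d,
                           maximum = TRUE, tol = 1e-8)
    h2 <- if (opt$objective >= ll[best]) opt$maximum else grid[best]
    converged <- is.finite(max(opt$objective, ll[best])) && (n > ncol(X) + 1L)
  }

  w <- pmax(h2 * d + (1 - h2), 1e-12)
  sw <- sqrt(w)
  Zx <- Xs / sw
  fit <- stats::lm.fit(Zx, ys / sw)
  rss <- sum(fit$residuals^2)
  s2 <- rss / n
  logL <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
  XtX <- crossprod(Zx)
  vcov <- tryCatch(s2 * solve(XtX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  b <- fit$coefficients
  names(b) <- colnames(X)
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- colnames(X)
  list(h2 = h2, sigma2p = s2, coef = b, se = se, logL = logL,
       converged = converged, ys = ys, Xs = Xs, d = d)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> ", x$kind, " trait, n = ", x$n, "\n", sep = "")
  cat("  h2 = ", signif(x$h2, 4),
      "  sigma2_g = ", signif(x$sigma2_g, 4),
      "  sigma2_e = ", signif(x$sigma2_e, 4), "\n", sep = "")
  cat("  logL = ", format(x$logL), if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Mixture chi-square p-value for a boundary LRT
#'
#' Null distribution of the heritability LRT statistic is the 50:50 mixture
#' of a point mass at zero and chi-square with 1 df, so
#' \code{p = 0.5 * P(chisq_1 >= stat)} for positive statistics and 0.5 at 0.
#'
#' @param stat non-negative LRT statistic
#' @return p-value
#' @export
vc_mixture_p <- function(stat) {
  0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Likelihood-ratio test of zero heritability
#'
#' Refits the model with \code{sigma2_g} constrained to 0 and compares
#' log-likelihoods; the p-value uses the boundary mixture
#' \code{0.5 chisq_0 + 0.5 chisq_1}.
#'
#' @param fit a converged [fit_polygenic()] result
#' @return list with \code{statistic}, \code{p.value}, \code{logL_null}
#' @export
heritability_test <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!fit$converged) stop("heritability_test requires a converged fit")
  null <- polygenic_ml(fit$y, fit$X, fit$eig, h2_fixed = 0)
  stat <- 2 * (fit$logL - null$logL)
  if (stat < -1e-6 * max(1, abs(fit$logL))) {
    stop("numeric error: constrained log-likelihood exceeds unconstrained ",
         "(optimizer failure, Lambda = ", format(stat), ")")
  }
  stat <- max(stat, 0)
  list(statistic = stat, p.value = vc_mixture_p(stat), logL_null = null$logL)
}

#' Likelihood-ratio test of a fixed effect
#'
#' Compares the polygenic model with and without the focal covariate,
#' re-estimating the variance components under each; the p-value is
#' chi-square with 1 df.  The coefficient and its standard error come from
#' the unconstrained fit (on the liability scale for binary traits).
#'
#' @param y trait vector
#' @param X covariate matrix including the focal column
#' @param A relationship matrix (or \code{NULL} with \code{eig})
#' @param focal name or index of the focal column
#' @param kind trait kind as in [fit_polygenic()]
#' @param eig optional precomputed [relationship_eigen()]
#' @return list with \code{coef}, \code{se}, \code{statistic}, \code{p.value},
#'   and the full \code{fit}
#' @export
fixed_effect_test <- function(y, X, A = NULL,
                              focal = ncol(X),
                              kind = c("continuous", "liability"),
                              eig = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (is.character(focal)) focal <- match(focal, colnames(X))
  if (is.na(focal) || focal < 1 || focal > ncol(X)) stop("focal column not found in X")

  if (all(X[, focal] == 0)) {
    fit <- fit_polygenic(y, X[, -focal, drop = FALSE], A, kind = kind, eig = eig)
    return(list(coef = 0, se = NA_real_, statistic = 0, p.value = 1, fit = fit))
  }
  full <- fit_polygenic(y, X, A, kind = kind, eig = eig)
  red <- fit_polygenic(y, X[, -focal, drop = FALSE], A, kind = kind,
                       eig = full$eig)
  stat <- max(0, 2 * (full$logL - red$logL))
  list(coef = unname(full$coef[focal]), se = unname(full$se[focal]),
       statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       fit = full)
}
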