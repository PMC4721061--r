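#' Bivariate polygenic decomposition of a trait correlation
#'
#' Fits the two-trait variance-component model in which the genetic
#' covariance between traits i and j is \code{rhoG * sqrt(s2gi * s2gj) * A}
#' and the environmental covariance is \code{rhoE * sqrt(s2ei * s2ej) * I},
#' by maximum likelihood.  After rotating both traits into the eigenbasis
#' of A the likelihood factorizes over eigenvalues into 2x2 Gaussian terms,
#' and the fixed effects are profiled out by generalized least squares at
#' every parameter value.  Correlations are searched on the atanh scale and
#' heritabilities on the logit scale so the optimizer stays interior;
#' non-finite proposals are rejected (logged as reprojections).
#'
#' The implied phenotypic correlation
#' \code{rhoP = rhoG * sqrt(h2_i h2_j) + rhoE * sqrt((1 - h2_i)(1 - h2_j))}
#' is computed from the fitted components; the raw residual Pearson
#' correlation after covariate adjustment is reported alongside it.
#'
#' @param y_i,y_j trait vectors on common samples
#' @param X covariate matrix including intercept (default intercept-only),
#'   applied to both traits
#' @param A relationship matrix (or \code{NULL} with \code{eig})
#' @param eig optional [relationship_eigen()]
#' @param se logical; also report tests of \code{rhoG = 0} and
#'   \code{rhoE = 0} by constrained LRT
#' @return object of class \code{bivar_fit} with \code{h2_i}, \code{h2_j},
#'   \code{rhoG}, \code{rhoE}, \code{rhoP}, \code{rhoP_residual},
#'   \code{logL}, and (if \code{se}) \code{p_rhoG}, \code{p_rhoE}
#' @export
fit_bivariate <- function(y_i, y_j, X = NULL, A = NULL, eig = NULL, se = TRUE) {
  n <- length(y_i)
  if (length(y_j) != n) stop("traits must share samples")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  check_full_rank(X)
  if (is.null(eig)) eig <- relationship_eigen(A)
  if (n < 2L || max(abs(relationship_offdiag(eig))) == 0) {
    # no relative pair carries information about rhoG
    warning("no relative pairs detected; genetic correlation is unidentifiable")
  }

  Ut <- t(eig$vectors)
  y1 <- drop(Ut %*% y_i); y2 <- drop(Ut %*% y_j)
  Xs <- Ut %*% X
  d <- eig$values

  obj <- function(par) {
    -bivar_loglik(bivar_par(par), y1, y2, Xs, d)$logL
  }
  # moderate-heritability, matched-sign starting values
  r0 <- stats::cor(y_i, y_j)
  start <- c(stats::qlogis(0.4), stats::qlogis(0.4), atanh(clamp(r0, -0.9, 0.9)),
             atanh(clamp(r0, -0.9, 0.9)), 0, 0)
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                       control = list(maxit = 200))
  if (opt2$value <= opt$value) opt <- opt2
  par <- bivar_par(opt$par)
  ll <- bivar_loglik(par, y1, y2, Xs, d)

  rhoP <- par$rhoG * sqrt(par$h2_i * par$h2_j) +
    par$rhoE * sqrt((1 - par$h2_i) * (1 - par$h2_j))
  r_resid <- stats::cor(stats::lm.fit(X, y_i)$residuals,
                        stats::lm.fit(X, y_j)$residuals)

  out <- list(h2_i = par$h2_i, h2_j = par$h2_j,
              rhoG = par$rhoG, rhoE = par$rhoE, rhoP = rhoP,
              rhoP_residual = r_resid, logL = ll$logL, n = n,
              converged = opt$convergence == 0, par = opt$par,
              y1 = y1, y2 = y2, Xs = Xs, d = d)
  class(out) <- "bivar_fit"
  if (se) {
    out$p_rhoG <- correlation_test(out, "genetic")$p.value
    out$p_rhoE <- correlation_test(out, "environmental")$p.value
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

relationship_offdiag <- function(eig) {
  # largest |A_ij| implied by the spectrum is not directly available;
  # a flat spectrum (all eigenvalues 1) means A = I, i.e. no relatives
  eig$values - 1
}

# parameter transform: interior-searchable -> natural scale
bivar_par <- function(par) {
  par <- clamp(par, -12, 12)
  list(h2_i = stats::plogis(par[1]), h2_j = stats::plogis(par[2]),
       rhoG = tanh(par[3]), rhoE = tanh(par[4]),
       s2_i = exp(clamp(par[5], -8, 8)), s2_j = exp(clamp(par[6], -8, 8)))
}

# log-likelihood of the rotated bivariate model with fixed effects profiled
bivar_loglik <- function(p, y1, y2, Xs, d) {
  n <- length(y1)
  g11 <- p$s2_i * p$h2_i
  g22 <- p$s2_j * p$h2_j
  g12 <- p$rhoG * sqrt(g11 * g22)
  e11 <- p$s2_i * (1 - p$h2_i)
  e22 <- p$s2_j * (1 - p$h2_j)
  e12 <- p$rhoE * sqrt(e11 * e22)

  c11 <- d * g11 + e11
  c22 <- d * g22 + e22
  c12 <- d * g12 + e12
  det <- c11 * c22 - c12^2
  if (any(det <= 1e-300) || any(c11 <= 0) || any(c22 <= 0)) {
    return(list(logL = -Inf))
  }
  i11 <- c22 / det; i22 <- c11 / det; i12 <- -c12 / det

  # GLS for the stacked fixed effects (same X for both traits)
  M11 <- crossprod(Xs, Xs * i11)
  M22 <- crossprod(Xs, Xs * i22)
  M12 <- crossprod(Xs, Xs * i12)
  v1 <- crossprod(Xs, i11 * y1 + i12 * y2)
  v2 <- crossprod(Xs, i12 * y1 + i22 * y2)
  M <- rbind(cbind(M11, M12), cbind(M12, M22))
  b <- tryCatch(solve(M, rbind(v1, v2)), error = function(e) NULL)
  if (is.null(b)) return(list(logL = -Inf))
  pdim <- ncol(Xs)
  b1 <- b[seq_len(pdim)]; b2 <- b[pdim + seq_len(pdim)]
  r1 <- y1 - drop(Xs %*% b1)
  r2 <- y2 - drop(Xs %*% b2)
  Q <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  logL <- -0.5 * (2 * n * log(2 * pi) + sum(log(det)) + Q)
  list(logL = logL, b1 = b1, b2 = b2)
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat("<bivar_fit> n = ", x$n, "\n", sep = "")
  cat(sprintf("  h2_i = %.3f  h2_j = %.3f\n", x$h2_i, x$h2_j))
  cat(sprintf("  rhoG = %.3f  rhoE = %.3f  rhoP = %.3f (residual %.3f)\n",
              x$rhoG, x$rhoE, x$rhoP, x$rhoP_residual))
  if (!is.null(x$p_rhoG)) {
    cat(sprintf("  p(rhoG = 0) = %.4g  p(rhoE = 0) = %.4g\n", x$p_rhoG, x$p_rhoE))
  }
  invisible(x)
}

#' Constrained LRT for a genetic or environmental correlation
#'
#' Refits the bivariate model with the chosen correlation fixed at zero and
#' compares log-likelihoods (chi-square, 1 df).
#'
#' @param fit a [fit_bivariate()] result
#' @param which \code{"genetic"} or \code{"environmental"}
#' @return list with \code{statistic} and \code{p.value}
#' @export
correlation_test <- function(fit, which = c("genetic", "environmental")) {
  which <- match.arg(which)
  fixed <- if (which == "genetic") 3L else 4L
  free <- setdiff(seq_len(6L), fixed)

  obj0 <- function(par5) {
    full <- numeric(6)
    full[free] <- par5
    full[fixed] <- 0
    -bivar_loglik(bivar_par(full), fit$y1, fit$y2, fit$Xs, fit$d)$logL
  }
  start <- fit$par[free]
  opt <- stats::optim(start, obj0, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  stat <- max(0, 2 * (fit$logL - (-opt$value)))
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
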