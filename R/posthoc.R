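#' Sobel mediation through an intermediate phenotype
#'
#' Quantifies how much of a methylation-outcome association runs through a
#' mediator by the product-of-coefficients method: model 1 regresses the
#' mediator on the methylation site (plus covariates), model 2 regresses
#' the outcome on the mediator, the site and the covariates; both are
#' polygenic fits.  The mediation parameter is \code{a * b} with the
#' delta-method standard error \code{sqrt(a^2 se_b^2 + b^2 se_a^2)} and a
#' standard-normal p-value.
#'
#' @param site methylation values (typically inverse-normalized)
#' @param mediator mediator phenotype (e.g. the HTGW indicator)
#' @param outcome outcome phenotype (e.g. T2D status)
#' @param X covariate matrix (intercept added internally)
#' @param A relationship matrix (or \code{NULL} with \code{eig})
#' @param kind_mediator,kind_outcome trait kinds for the two models
#' @param eig optional [relationship_eigen()]
#' @return object of class \code{mediation_result} with \code{a}, \code{se_a},
#'   \code{b}, \code{se_b}, \code{product}, \code{se}, \code{z}, \code{p.value}
#' @export
sobel_mediation <- function(site, mediator, outcome, X = NULL, A = NULL,
                            kind_mediator = "continuous",
                            kind_outcome = "continuous", eig = NULL) {
  n <- length(site)
  Xb <- cbind(`(Intercept)` = rep(1, n), X)
  if (is.null(eig)) eig <- relationship_eigen(A)

  m1 <- tryCatch(
    fixed_effect_test(mediator, cbind(Xb, site = site), focal = "site",
                      kind = kind_mediator, eig = eig),
    error = function(e) stop("mediation path a (site -> mediator) failed: ",
                             conditionMessage(e)))
  m2 <- tryCatch(
    fixed_effect_test(outcome, cbind(Xb, site = site, mediator = mediator),
                      focal = "mediator", kind = kind_outcome, eig = eig),
    error = function(e) stop("mediation path b (mediator -> outcome) failed: ",
                             conditionMessage(e)))

  sob <- sobel_parameter(m1$coef, m1$se, m2$coef, m2$se)
  structure(c(list(a = m1$coef, se_a = m1$se, b = m2$coef, se_b = m2$se), sob),
            class = "mediation_result")
}

#' Sobel product-of-coefficients statistic
#'
#' Mediation product \code{a * b}, its delta-method standard error
#' \code{sqrt(a^2 se_b^2 + b^2 se_a^2)}, the z-score and a two-sided
#' normal p-value.  Symmetric under exchange of the two (coefficient, SE)
#' pairs.
#'
#' @param a,se_a predictor-to-mediator coefficient and SE
#' @param b,se_b mediator-to-outcome coefficient and SE
#' @return list with \code{product}, \code{se}, \code{z}, \code{p.value}
#' @export
sobel_parameter <- function(a, se_a, b, se_b) {
  prod_ab <- a * b
  se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- if (se > 0) prod_ab / se else 0
  list(product = prod_ab, se = se, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation> a = %.4g (SE %.4g), b = %.4g (SE %.4g)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  a*b = %.4g, Sobel SE = %.4g, z = %.3f, p = %.4g\n",
              x$product, x$se, x$z, x$p.value))
  invisible(x)
}

#' Kullback-Leibler R-squared
#'
#' Likelihood-ratio-based pseudo-R-squared for nested models on the same
#' samples: \code{R2 = 1 - exp(-2 (logL_full - logL_null) / n)}.  For a
#' Gaussian linear model with independent errors this reduces exactly to
#' the classical OLS R-squared.
#'
#' @param logL_full,logL_null maximized log-likelihoods of nested models
#' @param n common sample size
#' @return fraction in [0, 1)
#' @export
kl_r2 <- function(logL_full, logL_null, n) {
  if (inherits(logL_full, "vc_fit")) logL_full <- logL_full$logL
  if (inherits(logL_null, "vc_fit")) logL_null <- logL_null$logL
  d <- logL_full - logL_null
  if (d < -1e-6 * max(1, abs(logL_null))) {
    stop("numeric error: full-model log-likelihood below null (", format(d), ")")
  }
  max(0, 1 - exp(-2 * max(d, 0) / n))
}

#' Model-comparison ladder
#'
#' Packages an ordered sequence of nested-model K-L R-squared values into a
#' comparison table with per-step increments and the total gain over the
#' base model.
#'
#' @param labels model labels (first = base)
#' @param r2 K-L R-squared per model
#' @param p optional per-step LRT p-values (length \code{length(r2) - 1})
#' @param n optional sample size
#' @return object of class \code{model_comparison}: data.frame with columns
#'   \code{model}, \code{kl_r2}, \code{delta_r2}, \code{p}; attribute
#'   \code{total_added} = final minus base R-squared
#' @export
model_comparison <- function(labels, r2, p = NULL, n = NA_integer_) {
  stopifnot(length(labels) == length(r2))
  if (any(r2 < 0 | r2 >= 1)) stop("K-L R2 must lie in [0, 1)")
  delta <- c(NA_real_, diff(r2))
  if (is.null(p)) p <- rep(NA_real_, length(r2) - 1L)
  out <- data.frame(model = labels, kl_r2 = r2, delta_r2 = delta,
                    p = c(NA_real_, p), stringsAsFactors = FALSE)
  attr(out, "total_added") <- r2[length(r2)] - r2[1L]
  attr(out, "n") <- n
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Forward-stepwise Kullback-Leibler ladder
#'
#' Starting from the base polygenic model \code{trait ~ covariates}, adds
#' the given sites one at a time in the given order, reporting the K-L
#' R-squared of every model (relative to the intercept-only polygenic
#' model), the per-step increment, and the per-step LRT p-value.  If a step
#' fails to fit, the partial ladder is returned with the failure annotated
#' in attribute \code{failed_step}.
#'
#' @param sites samples-by-sites matrix (columns added in order) or a
#'   single-site vector
#' @param trait trait vector
#' @param X covariate matrix (intercept added internally)
#' @param A relationship matrix (or \code{NULL} with \code{eig})
#' @param kind trait kind as in [fit_polygenic()]
#' @param eig optional [relationship_eigen()]
#' @return a [model_comparison()]
#' @export
stepwise_kl <- function(sites, trait, X = NULL, A = NULL,
                        kind = "continuous", eig = NULL) {
  sites <- as.matrix(sites)
  if (ncol(sites) < 1L) stop("stepwise_kl needs at least one site")
  if (is.null(colnames(sites))) colnames(sites) <- paste0("site", seq_len(ncol(sites)))
  n <- length(trait)
  Xb <- cbind(`(Intercept)` = rep(1, n), X)
  if (is.null(eig)) eig <- relationship_eigen(A)

  null0 <- fit_polygenic(trait, Xb[, 1, drop = FALSE], kind = kind, eig = eig)
  base <- fit_polygenic(trait, Xb, kind = kind, eig = eig)
  labels <- "Base"
  r2 <- kl_r2(base$logL, null0$logL, n)
  pstep <- numeric(0)
  prev <- base
  failed <- NULL
  Z <- Xb
  for (j in seq_len(ncol(sites))) {
    cn <- colnames(sites)[j]
    # a constant (zero-variance) column adds no information: delta R2 = 0
    if (stats::sd(sites[, j]) == 0) {
      labels <- c(labels, paste(labels[length(labels)], "+", cn))
      r2 <- c(r2, r2[length(r2)])
      pstep <- c(pstep, 1)
      next
    }
    Z2 <- cbind(Z, sites[, j, drop = FALSE])
    fit <- tryCatch(fit_polygenic(trait, Z2, kind = kind, eig = eig),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failed <- cn
      break
    }
    stat <- max(0, 2 * (fit$logL - prev$logL))
    labels <- c(labels, paste(labels[length(labels)], "+", cn))
    r2 <- c(r2, kl_r2(fit$logL, null0$logL, n))
    pstep <- c(pstep, stats::pchisq(stat, df = 1, lower.tail = FALSE))
    prev <- fit
    Z <- Z2
  }
  out <- model_comparison(labels, r2, pstep, n = n)
  attr(out, "failed_step") <- failed
  out
}
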