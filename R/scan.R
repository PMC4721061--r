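#' Genomic inflation factor (lambda_median)
#'
#' Median of the association chi-square statistics divided by the median of
#' the chi-square distribution with 1 df (0.4549...).
#'
#' @param chi2 vector of non-negative 1-df statistics
#' @return lambda_median
#' @export
genomic_inflation <- function(chi2) {
  chi2 <- chi2[is.finite(chi2)]
  if (!length(chi2)) stop("genomic_inflation needs at least one statistic")
  if (any(chi2 < 0)) stop("chi-square statistics must be non-negative")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Inflation-correct p-values
#'
#' Maps each p-value to its chi-square(1) statistic, divides by lambda, and
#' maps back.  Correction is only applied when lambda > 1: a deflation
#' factor (lambda < 1) indicates over-conservative statistics and dividing
#' by it would inflate significance, so p-values are then left unchanged.
#'
#' @param p p-value vector
#' @param lambda genomic inflation factor (> 0)
#' @return corrected p-value vector
#' @export
correct_inflation <- function(p, lambda) {
  stopifnot(lambda > 0)
  if (lambda <= 1) return(p)
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::pchisq(chi / lambda, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1);
#' delegates to \code{stats::p.adjust(method = "BH")}.
#'
#' @param p p-value vector in [0, 1]
#' @return q-value vector, order-preserving with respect to p
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Liability-scale odds ratio
#'
#' Converts a liability-scale regression coefficient to an odds ratio as
#' \code{OR = exp(sqrt(pi) * b)}, with \code{b} oriented so that positive
#' values increase risk.  (The source convention is sometimes printed with
#' a negative sign in the exponent; the printed odds ratios themselves
#' require the positive orientation used here, e.g. b = 0.65 -> OR = 3.16.)
#' Confidence bounds are transformed identically.
#'
#' @param b liability-scale coefficient (optionally with CI bounds)
#' @param ci optional length-2 vector of coefficient CI bounds
#' @return odds ratio, or list with \code{or} and \code{ci} when \code{ci}
#'   is supplied
#' @export
liability_or <- function(b, ci = NULL) {
  or <- exp(sqrt(pi) * b)
  if (is.null(ci)) return(or)
  list(or = or, ci = exp(sqrt(pi) * ci))
}

#' Ancestry principal components
#'
#' Top-k eigenvectors of the sample covariance of column-standardized
#' dosages.  Deterministic sign convention: within each component the
#' largest-magnitude loading is made positive.
#'
#' @param g samples x SNPs dosage matrix (complete; impute or filter first)
#' @param k number of components (0 gives an empty matrix)
#' @return samples x k score matrix with columns \code{PC1..PCk}
#' @export
ancestry_pcs <- function(g, k) {
  g <- as.matrix(g)
  if (k == 0) return(matrix(0, nrow(g), 0, dimnames = list(rownames(g), NULL)))
  sdv <- apply(g, 2, stats::sd)
  gs <- scale(g[, sdv > 0, drop = FALSE])
  sv <- svd(gs, nu = min(k, min(dim(gs))), nv = min(k, min(dim(gs))))
  rank_g <- sum(sv$d > 1e-8 * sv$d[1])
  if (k > rank_g) stop("k = ", k, " exceeds the rank (", rank_g, ") of the genotype matrix")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(k)))
  scores
}

#' Marker-level polygenic association scan
#'
#' For every marker, tests the marker as a fixed effect in the polygenic
#' model \code{trait ~ marker + covariates + g + e} by likelihood ratio,
#' with the heritability re-estimated under the full and the reduced model.
#' The relationship matrix is eigendecomposed once and rotated quantities
#' are reused across markers.  Per-marker convergence failures are recorded
#' and excluded from the inflation/FDR-corrected set, never silently
#' dropped.  After the per-marker pass, the genomic inflation factor
#' lambda_median is computed from the LRT statistics, p-values are
#' inflation-corrected (only when lambda > 1), and BH-FDR q-values are
#' attached.
#'
#' @param markers markers x samples numeric matrix (inverse-normalized
#'   methylation or additive dosages), rownames = marker ids
#' @param trait trait vector (0/1 for \code{kind = "liability"})
#' @param covariates covariate matrix (intercept added internally)
#' @param A relationship matrix (or \code{NULL} with \code{eig})
#' @param kind trait kind, as in [fit_polygenic()]
#' @param eig optional [relationship_eigen()]
#' @param lambda_correct \code{"auto"} (correct when lambda > 1) or
#'   \code{"off"}
#' @return object of class \code{scan_result}: list with \code{table}
#'   (marker, b, se, stat, p, p_corrected, q, n), \code{lambda_median},
#'   \code{failed} (marker ids), and \code{counts}
#' @export
association_scan <- function(markers, trait, covariates = NULL, A = NULL,
                             kind = c("continuous", "liability"),
                             eig = NULL, lambda_correct = c("auto", "off")) {
  kind <- match.arg(kind)
  lambda_correct <- match.arg(lambda_correct)
  markers <- as.matrix(markers)
  n <- length(trait)
  if (nrow(markers) > 0 && ncol(markers) != n) {
    stop("markers and trait are not sample-aligned")
  }
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  check_full_rank(X)

  if (nrow(markers) == 0L) {
    tab <- data.frame(marker = character(0), b = numeric(0), se = numeric(0),
                      stat = numeric(0), p = numeric(0),
                      p_corrected = numeric(0), q = numeric(0), n = integer(0))
    return(structure(list(table = tab, lambda_median = NA_real_,
                          failed = character(0),
                          counts = c(markers = 0L, converged = 0L)),
                     class = "scan_result"))
  }
  if (is.null(eig)) eig <- relationship_eigen(A)

  # liability traits: observed-scale fit, liability-scale reporting
  scale_fac <- 1
  if (kind == "liability") {
    if (!all(trait %in% c(0, 1))) stop("liability trait must be coded 0/1")
    K <- mean(trait)
    scale_fac <- 1 / stats::dnorm(stats::qnorm(1 - K))
  }

  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% trait)
  Xs <- Ut %*% X
  d <- eig$values
  Ms <- markers %*% eig$vectors     # rotated markers (markers x n)

  null_ll <- stats::optimize(vc_profile_loglik, c(0, 0.9999), ys = ys, Xs = Xs,
                             d = d, maximum = TRUE, tol = 1e-8)$objective
  null_ll <- max(null_ll, vc_profile_loglik(0, ys, Xs, d))

  ids <- rownames(markers)
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(markers)))
  res <- matrix(NA_real_, nrow(markers), 4,
                dimnames = list(ids, c("b", "se", "stat", "p")))
  pfull <- ncol(Xs) + 1L
  for (i in seq_len(nrow(markers))) {
    Zi <- cbind(Xs, Ms[i, ])
    fit <- tryCatch(scan_marker_fit(ys, Zi, d), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$logL)) next
    stat <- max(0, 2 * (fit$logL - null_ll))
    res[i, ] <- c(fit$b[pfull] * scale_fac, fit$se[pfull] * scale_fac, stat,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }

  failed <- ids[!is.finite(res[, "p"])]
  ok <- is.finite(res[, "p"])
  lambda <- if (any(ok)) genomic_inflation(res[ok, "stat"]) else NA_real_
  p_corr <- rep(NA_real_, nrow(res))
  if (any(ok)) {
    p_corr[ok] <- if (lambda_correct == "auto") {
      correct_inflation(res[ok, "p"], lambda)
    } else res[ok, "p"]
  }
  q <- rep(NA_real_, nrow(res))
  q[ok] <- bh_fdr(p_corr[ok])

  tab <- data.frame(marker = ids, b = res[, "b"], se = res[, "se"],
                    stat = res[, "stat"], p = res[, "p"],
                    p_corrected = p_corr, q = q, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, lambda_median = lambda, failed = failed,
                 counts = c(markers = nrow(markers), converged = sum(ok))),
            class = "scan_result")
}

# one-marker profile ML fit on pre-rotated data
scan_marker_fit <- function(ys, Zs, d) {
  opt <- stats::optimize(vc_profile_loglik, c(0, 0.9999), ys = ys, Xs = Zs,
                         d = d, maximum = TRUE, tol = 1e-7)
  ll0 <- vc_profile_loglik(0, ys, Zs, d)
  h2 <- if (opt$objective >= ll0) opt$maximum else 0
  logL <- max(opt$objective, ll0)
  n <- length(ys)
  w <- pmax(h2 * d + (1 - h2), 1e-12)
  sw <- sqrt(w)
  Z <- Zs / sw
  fit <- stats::lm.fit(Z, ys / sw)
  s2 <- sum(fit$residuals^2) / n
  vcov <- s2 * chol2inv(chol(crossprod(Z)))
  list(logL = logL, h2 = h2, b = fit$coefficients, se = sqrt(pmax(diag(vcov), 0)))
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> ", x$counts["markers"], " markers (",
      x$counts["converged"], " converged), lambda_median = ",
      signif(x$lambda_median, 4), "\n", sep = "")
  if (nrow(x$table)) {
    top <- x$table[order(x$table$p), ][seq_len(min(5L, nrow(x$table))), ]
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Median methylation difference between trait groups
#'
#' Difference of group medians (affected minus unaffected) of a beta-value
#' vector, the scale on which array effect sizes are usually reported.
#'
#' @param beta beta values for one probe
#' @param group 0/1 trait indicator
#' @return median(beta | group 1) - median(beta | group 0)
#' @export
group_median_diff <- function(beta, group) {
  stats::median(beta[group == 1], na.rm = TRUE) -
    stats::median(beta[group == 0], na.rm = TRUE)
}
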