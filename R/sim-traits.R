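#' Eigendecomposition of a relationship matrix
#'
#' Decomposes A once so that every polygenic likelihood, simulator and scan
#' can reuse it.  Small negative eigenvalues (numerical noise) are clipped
#' to zero; a genuinely indefinite matrix is refused.
#'
#' @param A additive relationship matrix
#' @return list with \code{vectors}, \code{values} (clipped), \code{ids}
#' @export
relationship_eigen <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol) {
    stop("numeric error: relationship matrix is not positive semi-definite ",
         "(min eigenvalue ", format(min(e$values)), ")")
  }
  list(vectors = e$vectors, values = pmax(e$values, 0), ids = rownames(A))
}

# draw one MVN(0, s2 * A) vector from a precomputed eigendecomposition
rmvn_eig <- function(eig, s2 = 1, m = 1) {
  n <- length(eig$values)
  z <- matrix(stats::rnorm(n * m), n, m)
  eig$vectors %*% (sqrt(pmax(eig$values, 0) * s2) * z)
}

#' Simulate a polygenic quantitative trait
#'
#' Generates \code{y = X b + g + e} with \code{g ~ MVN(0, h2 * A)} and
#' independent \code{e ~ N(0, 1 - h2)}, i.e. unit total variance before
#' covariate effects.
#'
#' @param ped a \code{fam_pedigree} (used for sample ids)
#' @param A relationship matrix (ignored when \code{eig} is given)
#' @param h2 generative heritability in [0, 1]
#' @param X optional covariate matrix
#' @param b optional covariate coefficients (length \code{ncol(X)})
#' @param seed optional integer seed
#' @param eig optional [relationship_eigen()] of A
#' @return named numeric vector of trait values
#' @export
simulate_polygenic_trait <- function(ped, A, h2, X = NULL, b = NULL,
                                     seed = NULL, eig = NULL) {
  stopifnot(h2 >= 0, h2 <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eig)) eig <- relationship_eigen(A)
  n <- length(eig$values)
  g <- drop(rmvn_eig(eig, s2 = h2))
  e <- stats::rnorm(n, sd = sqrt(1 - h2))
  y <- g + e
  if (!is.null(X)) y <- y + drop(as.matrix(X) %*% b)
  names(y) <- if (!is.null(eig$ids)) eig$ids else ped$sample_id
  y
}

#' Dichotomize a liability at an empirical threshold
#'
#' The threshold is the empirical (1 - prevalence) quantile of the liability,
#' so the realized prevalence matches the target exactly at finite n
#' (up to one individual).
#'
#' @param liability numeric liability vector
#' @param prevalence target fraction affected, in (0, 1)
#' @return integer 0/1 vector (1 = affected), names preserved
#' @export
simulate_binary_trait <- function(liability, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  thr <- stats::quantile(liability, probs = 1 - prevalence, type = 1, names = FALSE)
  y <- as.integer(liability > thr)
  names(y) <- names(liability)
  y
}

#' Simulate a correlated trait pair under the bivariate polygenic model
#'
#' Genetic effects for the two traits share the relationship structure A and
#' have cross-trait correlation \code{rhoG}; environmental residuals are
#' individual-specific with correlation \code{rhoE}.  Each trait has unit
#' total variance, so the implied phenotypic correlation is
#' \code{rhoG * sqrt(h2_i * h2_j) + rhoE * sqrt((1 - h2_i) * (1 - h2_j))}.
#'
#' @inheritParams simulate_polygenic_trait
#' @param h2_i,h2_j trait heritabilities
#' @param rhoG,rhoE genetic and environmental correlations in [-1, 1]
#' @return matrix with two named columns \code{y_i}, \code{y_j}
#' @export
simulate_bivariate <- function(ped, A, h2_i, h2_j, rhoG, rhoE,
                               seed = NULL, eig = NULL) {
  for (h in c(h2_i, h2_j)) stopifnot(h >= 0, h <= 1)
  if (abs(rhoG) > 1 || abs(rhoE) > 1) {
    stop("configuration error: correlations must lie in [-1, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eig)) eig <- relationship_eigen(A)
  n <- length(eig$values)

  SigG <- matrix(c(h2_i, rhoG * sqrt(h2_i * h2_j),
                   rhoG * sqrt(h2_i * h2_j), h2_j), 2, 2)
  SigE <- matrix(c(1 - h2_i, rhoE * sqrt((1 - h2_i) * (1 - h2_j)),
                   rhoE * sqrt((1 - h2_i) * (1 - h2_j)), 1 - h2_j), 2, 2)
  for (S in list(SigG, SigE)) {
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop("configuration error: implied 2x2 covariance is not PSD")
    }
  }
  chol2 <- function(S) {            # tolerant 2x2 factor (handles rho = +/-1)
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2)
  }
  LG <- chol2(SigG); LE <- chol2(SigE)
  ZG <- matrix(stats::rnorm(2 * n), n, 2) %*% t(LG)
  g <- eig$vectors %*% (sqrt(eig$values) * ZG)
  e <- matrix(stats::rnorm(2 * n), n, 2) %*% t(LE)
  out <- g + e
  colnames(out) <- c("y_i", "y_j")
  rownames(out) <- if (!is.null(eig$ids)) eig$ids else ped$sample_id
  out
}
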