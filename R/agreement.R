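#' Bland-Altman agreement analysis
#'
#' Differences are oriented method2 minus method1 (e.g. pyrosequencing
#' minus array).  Limits of agreement are mean difference +/- 1.96 times
#' the SD of the differences; pairs outside the limits are counted, and
#' the (pair mean, difference) coordinates needed for the agreement plot
#' are returned.
#'
#' @param x method-1 values
#' @param y method-2 values, paired with \code{x}
#' @return object of class \code{agreement_result} with \code{mean_diff},
#'   \code{sd_diff}, \code{limits} (lower, upper), \code{n_outside},
#'   \code{n}, and \code{points} (data.frame mean/diff/outside)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("bland_altman needs >= 3 pairs")
  d <- y - x
  md <- mean(d)
  sdd <- stats::sd(d)
  lim <- c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
  outside <- d < lim[1] | d > lim[2]
  structure(list(mean_diff = md, sd_diff = sdd, limits = lim,
                 n_outside = sum(outside), n = length(d),
                 points = data.frame(mean = (x + y) / 2, diff = d,
                                     outside = outside)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean diff = %.4g, LoA = (%.4g, %.4g), %d outside\n",
              x$n, x$mean_diff, x$limits[1], x$limits[2], x$n_outside))
  invisible(x)
}

#' Pitman's test of unequal variances for paired samples
#'
#' Tests whether two paired measurements have equal variances by testing
#' the correlation between the pair differences and the pair sums
#' (t-distribution, n - 2 df, two-sided).
#'
#' @param x,y paired numeric vectors, at least 4 pairs
#' @return list with \code{r}, \code{statistic}, \code{df}, \code{p.value}
#' @export
pitman_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("pitman_test needs >= 4 pairs")
  d <- y - x
  s <- y + x
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d))) ||
      stats::sd(s) <= 1e-10 * max(1, abs(mean(s)))) {
    stop("degenerate input: zero variance in pair differences or sums")
  }
  r <- stats::cor(d, s)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, statistic = tt, df = n - 2,
       p.value = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks, with the p-value from
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 df (two-sided).
#'
#' @param x,y paired numeric vectors, at least 3 pairs
#' @return list with \code{rho}, \code{statistic}, \code{df}, \code{p.value}
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_corr needs >= 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    return(list(rho = rho, statistic = sign(rho) * Inf, df = n - 2, p.value = 0))
  }
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, statistic = tt, df = n - 2,
       p.value = 2 * stats::pt(-abs(tt), df = n - 2))
}
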