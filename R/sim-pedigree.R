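#' Simulate three-generation extended pedigrees
#'
#' Builds \code{n_families} three-generation families: a founder couple,
#' their children (some of whom marry in founder spouses), and
#' grandchildren.  Family sizes are drawn around the per-family mean and
#' then balanced so the cohort totals exactly \code{cfg$n_individuals}
#' (always within 10\% of the target, as the downstream calibrations
#' assume).
#'
#' @param cfg a [sim_config()]
#' @return a \code{fam_pedigree}
#' @export
simulate_pedigrees <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_families
  target <- cfg$n_individuals
  if (target < 3L * nf) stop("configuration error: need >= 3 individuals per family")

  # per-family sizes: Poisson spread around the mean, then balanced to sum
  mean_size <- target / nf
  sizes <- pmax(3L, stats::rpois(nf, mean_size))
  while (sum(sizes) != target) {
    if (sum(sizes) < target) {
      i <- sample.int(nf, 1L)
      sizes[i] <- sizes[i] + 1L
    } else {
      big <- which(sizes > 3L)
      i <- if (length(big) > 1L) sample(big, 1L) else big
      sizes[i] <- sizes[i] - 1L
    }
  }

  fams <- lapply(seq_len(nf), function(f) {
    fam <- build_family(sizes[f], cfg$mean_children_g2, cfg$mean_children_g3)
    fam$fid <- sprintf("FAM%02d", f)
    fam$iid <- sprintf("F%02d_I%03d", f, seq_len(nrow(fam)))
    fam$pat <- ifelse(fam$pat_idx == 0L, "0", sprintf("F%02d_I%03d", f, fam$pat_idx))
    fam$mat <- ifelse(fam$mat_idx == 0L, "0", sprintf("F%02d_I%03d", f, fam$mat_idx))
    fam[, c("fid", "iid", "pat", "mat", "sex")]
  })
  pedigree(do.call(rbind, fams))
}

# One family of exactly `size` members; indices 1 (father) and 2 (mother)
# are the G1 founder couple.  Returns pat_idx/mat_idx as integer indices
# (0 = founder) plus sex.
build_family <- function(size, mean_g2, mean_g3) {
  sex <- c(1L, 2L)
  pat <- c(0L, 0L)
  mat <- c(0L, 0L)
  gen <- c(1L, 1L)
  spouse_of <- c(2L, 1L)
  budget <- size - 2L

  nc2 <- min(budget, 1L + stats::rpois(1L, max(mean_g2 - 1, 0)))
  g2 <- integer(0)
  for (k in seq_len(nc2)) {
    sex <- c(sex, sample(1:2, 1L)); pat <- c(pat, 1L); mat <- c(mat, 2L)
    gen <- c(gen, 2L); spouse_of <- c(spouse_of, 0L)
    g2 <- c(g2, length(sex))
  }
  budget <- budget - nc2

  while (budget > 0L) {
    unmarried <- g2[spouse_of[g2] == 0L]
    if (length(unmarried)) {
      child <- unmarried[1L]
      sex <- c(sex, 3L - sex[child]); pat <- c(pat, 0L); mat <- c(mat, 0L)
      gen <- c(gen, 2L); spouse_of <- c(spouse_of, child)
      sp <- length(sex); spouse_of[child] <- sp
      budget <- budget - 1L
      if (budget > 0L) {
        k3 <- min(budget, 1L + stats::rpois(1L, max(mean_g3 - 1, 0)))
        fa <- if (sex[child] == 1L) child else sp
        mo <- if (sex[child] == 1L) sp else child
        for (j in seq_len(k3)) {
          sex <- c(sex, sample(1:2, 1L)); pat <- c(pat, fa); mat <- c(mat, mo)
          gen <- c(gen, 3L); spouse_of <- c(spouse_of, 0L)
        }
        budget <- budget - k3
      }
    } else {
      # all G2 children married: grow an existing G3 sibship or the G2 sibship
      couples <- g2[spouse_of[g2] > 0L]
      if (length(couples)) {
        child <- if (length(couples) > 1L) sample(couples, 1L) else couples
        sp <- spouse_of[child]
        fa <- if (sex[child] == 1L) child else sp
        mo <- if (sex[child] == 1L) sp else child
        sex <- c(sex, sample(1:2, 1L)); pat <- c(pat, fa); mat <- c(mat, mo)
        gen <- c(gen, 3L); spouse_of <- c(spouse_of, 0L)
      } else {
        sex <- c(sex, sample(1:2, 1L)); pat <- c(pat, 1L); mat <- c(mat, 2L)
        gen <- c(gen, 2L); spouse_of <- c(spouse_of, 0L)
        g2 <- c(g2, length(sex))
      }
      budget <- budget - 1L
    }
  }
  data.frame(pat_idx = pat, mat_idx = mat, sex = sex, gen = gen)
}
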