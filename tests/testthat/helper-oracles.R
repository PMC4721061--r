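# Shared fixtures and independent oracles, all built in code.

ped_from_text <- function(txt) {
  df <- utils::read.table(text = txt, header = FALSE, colClasses = "character")
  names(df) <- c("fid", "iid", "pat", "mat", "sex")
  pedigree(df)
}

trio_text <- "
FAM1 dad 0 0 1
FAM1 mom 0 0 2
FAM1 kid dad mom 1
"

founder_ped <- function(n) {
  ped_from_text(paste(sprintf("F1 id%d 0 0 %d", seq_len(n), rep(1:2, length.out = n)),
                      collapse = "\n"))
}

# 12-member three-generation family: full sibs (c1,c2,c3), married-in
# founders (s1,s2,s3), cousins (k1,k2 vs k3), half sibs (k1 vs k4)
cousin_ped <- function() {
  ped_from_text("
F1 gp1 0 0 1
F1 gp2 0 0 2
F1 c1 gp1 gp2 1
F1 c2 gp1 gp2 2
F1 c3 gp1 gp2 1
F1 s1 0 0 2
F1 s2 0 0 1
F1 s3 0 0 2
F1 k1 c1 s1 1
F1 k2 c1 s1 2
F1 k3 s2 c2 1
F1 k4 c1 s3 2
")
}

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# unique founder alleles, Mendelian transmission, IBD sharing averaged
# over replicates.  Independent of the tabular recursion under test.
gene_drop_A <- function(ped, nrep = 1e5) {
  fa <- attr(ped, "father_idx")
  mo <- attr(ped, "mother_idx")
  n <- nrow(ped)
  a1 <- matrix(0L, nrep, n)
  a2 <- matrix(0L, nrep, n)
  nxt <- 1L
  for (i in attr(ped, "topo_order")) {
    if (is.na(fa[i])) {
      a1[, i] <- nxt; nxt <- nxt + 1L
    } else {
      pick <- stats::runif(nrep) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
    }
    if (is.na(mo[i])) {
      a2[, i] <- nxt; nxt <- nxt + 1L
    } else {
      pick <- stats::runif(nrep) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$sample_id, ped$sample_id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(a1[, i] == a2[, i])
    for (j in seq_len(n)) {
      if (j <= i) next
      s <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
        (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      A[i, j] <- A[j, i] <- mean(s) / 2
    }
  }
  A
}

# Dense multivariate-normal profile log-likelihood (no eigendecomposition):
# V = h2 A + (1 - h2) I, GLS fixed effects, ML residual variance.
dense_vc_loglik <- function(h2, y, X, A) {
  n <- length(y)
  V <- h2 * A + (1 - h2) * diag(n)
  ch <- chol(V)
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  b <- qr.coef(qr(Xw), yw)
  r <- yw - Xw %*% b
  s2 <- sum(r^2) / n
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
}

# small shared study-scale pedigree (built once per test run)
study_eig <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- simulate_pedigrees(sim_config(seed = 7))
      cache <<- list(ped = ped, eig = relationship_eigen(relationship_matrix(ped)))
    }
    cache
  }
})

small_eig <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- simulate_pedigrees(sim_config(seed = 11, n_families = 10,
                                           n_individuals = 220))
      cache <<- list(ped = ped, eig = relationship_eigen(relationship_matrix(ped)))
    }
    cache
  }
})
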