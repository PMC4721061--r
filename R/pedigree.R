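#' Read a pedigree file
#'
#' Reads a whitespace- or tab-delimited pedigree file with columns
#' FID IID PAT MAT SEX (the first five columns of a PLINK \code{.fam} file).
#' Missing parents are encoded by \code{missing} (default \code{"0"}).
#' Sex is coded 1 = male, 2 = female (the strings \code{"M"}/\code{"F"} and
#' \code{"male"}/\code{"female"} are also accepted).
#'
#' @param path path to the pedigree file.
#' @param missing token marking an unknown parent.
#' @param header logical; does the file carry a header line?
#' @return a validated \code{fam_pedigree} object (see [pedigree()]).
#'   Row order of the file is preserved and becomes the canonical sample
#'   order for all downstream matrices.
#' @export
read_pedigree <- function(path, missing = "0", header = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.table(path, header = header, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("pedigree file must have >= 5 columns (FID IID PAT MAT SEX)")
  df <- df[, 1:5]
  names(df) <- c("fid", "iid", "pat", "mat", "sex")
  pedigree(df, missing = missing)
}

#' Construct and validate a pedigree
#'
#' @param df data.frame with columns \code{fid}, \code{iid}, \code{pat},
#'   \code{mat}, \code{sex}.
#' @param missing token marking an unknown parent.
#' @return object of class \code{fam_pedigree}: the validated data.frame with
#'   normalized sex coding (\code{1} male, \code{2} female), a \code{sample_id}
#'   column used to label all downstream matrices, and attributes
#'   \code{missing} and \code{founder} (logical: both parents unknown).
#' @export
pedigree <- function(df, missing = "0") {
  req <- c("fid", "iid", "pat", "mat", "sex")
  if (!all(req %in% names(df))) {
    stop("pedigree needs columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  }
  df <- df[, req]
  for (cn in req) df[[cn]] <- as.character(df[[cn]])
  df$sex <- normalize_sex(df$sex)

  key <- paste(df$fid, df$iid, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate individual id(s) within family: ",
         paste(unique(df$iid[dup]), collapse = ", "))
  }

  pkey <- paste(df$fid, df$pat, sep = "\r")
  mkey <- paste(df$fid, df$mat, sep = "\r")
  fa <- match(pkey, key)
  mo <- match(mkey, key)
  fa[df$pat == missing] <- NA_integer_
  mo[df$mat == missing] <- NA_integer_

  bad_fa <- which(df$pat != missing & is.na(fa))
  bad_mo <- which(df$mat != missing & is.na(mo))
  if (length(bad_fa) || length(bad_mo)) {
    stop("named parent(s) absent from their family: ",
         paste(unique(c(df$pat[bad_fa], df$mat[bad_mo])), collapse = ", "))
  }
  if (any(df$sex[fa[!is.na(fa)]] != 1L)) {
    stop("validation error: father(s) not coded male: ",
         paste(unique(df$iid[fa[!is.na(fa)]][df$sex[fa[!is.na(fa)]] != 1L]), collapse = ", "))
  }
  if (any(df$sex[mo[!is.na(mo)]] != 2L)) {
    stop("validation error: mother(s) not coded female: ",
         paste(unique(df$iid[mo[!is.na(mo)]][df$sex[mo[!is.na(mo)]] != 2L]), collapse = ", "))
  }

  ord <- ped_topological_order(fa, mo, df$iid)

  df$sample_id <- if (anyDuplicated(df$iid)) paste(df$fid, df$iid, sep = ":") else df$iid
  attr(df, "missing") <- missing
  attr(df, "father_idx") <- fa
  attr(df, "mother_idx") <- mo
  attr(df, "topo_order") <- ord
  attr(df, "founder") <- is.na(fa) & is.na(mo)
  class(df) <- c("fam_pedigree", "data.frame")
  df
}

# Kahn topological sort over the parent -> child DAG; errors with the cycle
# membership if ancestry is circular (e.g. an individual is its own father).
ped_topological_order <- function(fa, mo, iid) {
  n <- length(fa)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) {
        if (p == i) stop("cyclic ancestry: individual ", iid[i], " is its own ancestor")
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("cyclic ancestry involving: ",
         paste(iid[setdiff(seq_len(n), ord)], collapse = ", "))
  }
  ord
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "m", "male")] <- 1L
  out[x %in% c("2", "f", "female")] <- 2L
  if (anyNA(out)) stop("unrecognized sex code(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @export
print.fam_pedigree <- function(x, ...) {
  cat("<fam_pedigree> ", nrow(x), " individuals in ", length(unique(x$fid)),
      " families (", sum(attr(x, "founder")), " founders)\n", sep = "")
  invisible(x)
}

#' Number of individuals, founders, families
#' @param ped a \code{fam_pedigree}
#' @return named integer vector
#' @export
ped_summary <- function(ped) {
  c(n = nrow(ped), founders = sum(attr(ped, "founder")),
    families = length(unique(ped$fid)))
}

#' Write a pedigree file
#'
#' Writes the five PLINK-style columns, whitespace-delimited, no header.
#' @param ped a \code{fam_pedigree}
#' @param path output path
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped)[, c("fid", "iid", "pat", "mat", "sex")],
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Additive genetic relationship matrix
#'
#' Computes the numerator relationship matrix A (twice the kinship matrix)
#' by the recursive tabular method: founders are taken as unrelated and
#' non-inbred, and for an individual i with parents f and m,
#' \code{A[i, j] = (A[f, j] + A[m, j]) / 2} for j already processed and
#' \code{A[i, i] = 1 + A[f, m] / 2}.  Parents are processed before their
#' offspring (a topological sort makes input row order irrelevant), missing
#' parents contribute 0, and the matrix is block-diagonal by family.
#'
#' @param ped a validated \code{fam_pedigree}
#' @return symmetric matrix with dimnames = sample ids in file order;
#'   diagonal is 1 for non-inbred individuals and may exceed 1 under
#'   inbreeding loops.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "fam_pedigree"))
  n <- nrow(ped)
  fa <- attr(ped, "father_idx")
  mo <- attr(ped, "mother_idx")
  A <- matrix(0, n, n, dimnames = list(ped$sample_id, ped$sample_id))
  for (i in attr(ped, "topo_order")) {
    f <- fa[i]; m <- mo[i]
    rf <- if (!is.na(f)) A[f, ] else numeric(n)
    rm_ <- if (!is.na(m)) A[m, ] else numeric(n)
    row <- (rf + rm_) / 2
    A[i, ] <- row
    A[, i] <- row
    A[i, i] <- 1 + (if (!is.na(f) && !is.na(m)) A[f, m] / 2 else 0)
  }
  A
}

#' Write / read a relationship matrix as TSV
#'
#' Tab-separated with a header row of ids and an id column.
#' @param A relationship matrix with dimnames
#' @param path file path
#' @export
write_relationship <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship
#' @export
read_relationship <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  storage.mode(A) <- "double"
  A
}
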