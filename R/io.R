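#' Tabular writers and readers
#'
#' All pipeline tables are tab-separated with a header row.  Matrices are
#' written with their rownames in a leading \code{id} column, so every file
#' round-trips losslessly through the matching reader.
#'
#' @param x data.frame or matrix
#' @param path file path
#' @name famews_io
NULL

#' @rdname famews_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname famews_io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' @rdname famews_io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname famews_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a methylation matrix to three TSV files
#'
#' Writes \code{<prefix>_beta.tsv}, \code{<prefix>_detection.tsv} and
#' \code{<prefix>_annotation.tsv}.
#' @param m a [methylation_matrix()]
#' @param prefix path prefix
#' @return the three paths, invisibly
#' @export
write_methylation <- function(m, prefix) {
  paths <- paste0(prefix, c("_beta.tsv", "_detection.tsv", "_annotation.tsv"))
  write_matrix_tsv(m$beta, paths[1])
  write_matrix_tsv(m$detection, paths[2])
  write_tsv(m$annotation, paths[3])
  invisible(paths)
}

#' Read a methylation matrix written by [write_methylation()]
#' @param prefix path prefix
#' @return a [methylation_matrix()]
#' @export
read_methylation <- function(prefix) {
  beta <- read_matrix_tsv(paste0(prefix, "_beta.tsv"))
  det <- read_matrix_tsv(paste0(prefix, "_detection.tsv"))
  ann <- read_tsv(paste0(prefix, "_annotation.tsv"))
  methylation_matrix(beta, det, ann)
}

#' Write / read a flat key-value configuration file
#' @param cfg a [sim_config()]
#' @param path file path
#' @export
write_sim_config <- function(cfg, path) {
  flat <- utils::modifyList(unclass(cfg), list(
    bivariate = NULL, effect_sites = NULL, cell_alpha = NULL))
  lines <- vapply(names(flat), function(k) {
    paste0(k, "=", paste(flat[[k]], collapse = ","))
  }, character(1))
  lines <- c(lines,
             paste0("bivariate=", paste(unlist(cfg$bivariate), collapse = ",")),
             paste0("cell_alpha=", paste(cfg$cell_alpha, collapse = ",")))
  if (!is.null(cfg$effect_sites)) {
    lines <- c(lines, paste0("effect_sites=",
                             paste(cfg$effect_sites$probe, cfg$effect_sites$beta_diff,
                                   sep = ":", collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
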