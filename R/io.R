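#' Read and write feature tables as TSV
#'
#' On disk a feature table is features x samples (the orientation amplicon
#' toolkits export): first column feature IDs, header row of sample IDs.
#' In memory tables are samples x features.
#'
#' @param path File path.
#' @param sample_meta Optional named character vector (sample -> host) to
#'   attach on read.
#' @return `read_feature_table_tsv`: a `feature_table`.
#' @export
read_feature_table_tsv <- function(path, sample_meta = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- df[[1]]
  feature_table(mat, sample_meta)
}

#' @rdname read_feature_table_tsv
#' @param table A `feature_table` to write.
#' @export
write_feature_table_tsv <- function(table, path) {
  df <- data.frame(`Feature ID` = colnames(table$counts),
                   t(table$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(table$provenance))
    jsonlite::write_json(table$provenance, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write labeled square distance matrices as TSV
#'
#' First row and first column carry the sample IDs.
#' @param path File path.
#' @return `read_dist_tsv`: a labeled symmetric matrix.
#' @export
read_dist_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE)
  as_dist_matrix(as.matrix(df))
}

#' @rdname read_dist_tsv
#' @param dm Labeled symmetric matrix to write.
#' @export
write_dist_tsv <- function(dm, path) {
  df <- data.frame(sample = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a labeled distance matrix
#'
#' Checks squareness, unique labels, symmetry within 1e-12 of the matrix
#' scale, non-negativity, and zero diagonal.
#' @param dm Matrix to validate.
#' @return The matrix, with dimnames synchronised.
#' @export
as_dist_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must be labeled")
  if (anyDuplicated(rownames(dm))) stop("duplicate labels in distance matrix")
  colnames(dm) <- rownames(dm)
  if (max(abs(dm - t(dm))) > 1e-12 * max(1, max(abs(dm))))
    stop("distance matrix is not symmetric")
  if (any(dm < 0)) stop("negative distances")
  if (any(abs(diag(dm)) > 1e-12)) stop("nonzero diagonal")
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  dm
}

#' Read/write FASTA as a named character vector
#' @param path File path.
#' @return `read_fasta_seqs`: named character vector of uppercase sequences.
#' @export
read_fasta_seqs <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""),
                 character(1))
  stats::setNames(seqs, names(dna))
}

#' @rdname read_fasta_seqs
#' @param seqs Named character vector of sequences to write.
#' @export
write_fasta_seqs <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(as.character(seqs[[i]]), con)
  }
  invisible(path)
}
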