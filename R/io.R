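#' Write a genes-by-patients matrix as tab-separated text
#'
#' One row per gene; the first column holds the gene identifier and the
#' header row carries patient identifiers.
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_col name of the identifier column.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with gene identifiers as row names and patient
#'   identifiers as column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
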