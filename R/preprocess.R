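#' Counts per million
#'
#' Library-size normalization: `cpm[g, s] = counts[g, s] * 1e6 /
#' colsum(s)`.
#'
#' @param counts non-negative genes x patients matrix.
#' @return a matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("zero library size for patient(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, cs, "/") * 1e6
}

#' Filter genes with low expression
#'
#' Keeps the genes whose CPM reaches `min_cpm` in at least `min_samples`
#' patients (so unexpressed, all-zero genes are always removed); row order
#' is preserved.
#'
#' @param counts non-negative genes x patients matrix with gene row names.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of patients at or above the threshold
#'   (default 3).
#' @return character vector of kept gene identifiers.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 3) {
  if (min_samples > ncol(counts))
    stop("invalid config: min_samples exceeds the number of patients")
  if (any(counts < 0)) stop("counts must be non-negative")
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  rownames(counts)[keep]
}

#' Upper-quartile FPKM normalization
#'
#' FPKM with the library size replaced by the sample's 75th percentile of
#' positive gene counts: `fpkm_uq[g, s] = counts[g, s] * 1e9 / (uq(s) *
#' length(g))`. The quartile is taken over positive counts only, so sparse
#' columns do not drag it to zero.
#'
#' @param counts non-negative genes x patients matrix.
#' @param gene_lengths positive gene lengths in bases, named by gene or in
#'   row order.
#' @return a matrix of the same shape.
#' @export
fpkm_uq <- function(counts, gene_lengths) {
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing) > 0)
      stop("gene lengths missing for: ", paste(utils::head(missing, 5),
                                               collapse = ", "))
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  uq <- apply(counts, 2, function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0) 0 else stats::quantile(pos, 0.75, names = FALSE)
  })
  if (any(uq == 0)) {
    bad <- colnames(counts)[uq == 0]
    if (is.null(bad)) bad <- which(uq == 0)
    stop("zero upper-quartile count for patient(s): ",
         paste(bad, collapse = ", "))
  }
  sweep(counts / gene_lengths, 2, uq, "/") * 1e9
}

#' Clean a gene-level copy-number matrix
#'
#' Drops genes that are missing in every patient and mean-imputes the
#' remaining missing entries per gene, reporting the imputed count.
#'
#' @param cna genes x patients real matrix, `NA` allowed.
#' @return the cleaned matrix, with attributes `dropped_genes` and
#'   `n_imputed`.
#' @export
clean_cna <- function(cna) {
  all_na <- rowSums(!is.na(cna)) == 0
  dropped <- rownames(cna)[all_na]
  out <- cna[!all_na, , drop = FALSE]
  n_imp <- sum(is.na(out))
  if (n_imp > 0) {
    means <- rowMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- means[idx[, 1]]
    message(sprintf("clean_cna: imputed %d missing entries", n_imp))
  }
  if (length(dropped) > 0)
    message(sprintf("clean_cna: dropped %d all-missing genes",
                    length(dropped)))
  attr(out, "dropped_genes") <- dropped
  attr(out, "n_imputed") <- n_imp
  out
}

#' Restrict paired omics matrices to shared genes and patients
#'
#' Both matrices are reduced to the intersection of their gene identifiers,
#' placed in one canonical (sorted) order, and to the patients present in
#' both sources (and in the clinical table, if given).
#'
#' @param expr_matrix,cna_matrix matrices with gene row names and patient
#'   column names.
#' @param clinical optional clinical data frame with a `patient_id` column;
#'   patients absent from it are dropped too.
#' @return a list with elements `expr` and `cna`, row/column aligned.
#' @export
match_genes <- function(expr_matrix, cna_matrix, clinical = NULL) {
  genes <- sort(intersect(rownames(expr_matrix), rownames(cna_matrix)))
  if (length(genes) == 0) stop("no genes shared between the two sources")
  patients <- intersect(colnames(expr_matrix), colnames(cna_matrix))
  if (!is.null(clinical)) patients <- intersect(patients,
                                                clinical$patient_id)
  if (length(patients) == 0) stop("no patients shared across inputs")
  list(expr = expr_matrix[genes, patients, drop = FALSE],
       cna = cna_matrix[genes, patients, drop = FALSE])
}

#' Per-gene min-max scaling into \[0, 1\]
#'
#' Each gene row is transformed as `(x - min) / (max - min)`, so every
#' retained gene attains both 0 and 1. Constant genes have no defined scale
#' and are dropped; their identifiers are reported in the `dropped_genes`
#' attribute.
#'
#' @param m finite genes x patients matrix.
#' @param source_tag label for the omics source ("expression" or "cna").
#' @param per_gene scale each gene row to its own range (default); with
#'   `FALSE`, one global min/max is used for the whole matrix (constant
#'   matrices are rejected).
#' @return the scaled matrix (class `scaled_matrix`) with attributes
#'   `source_tag` and `dropped_genes`.
#' @export
minmax_scale <- function(m, source_tag = "expression", per_gene = TRUE) {
  if (any(!is.finite(m))) stop("matrix must be finite")
  if (!per_gene) {
    rng <- range(m)
    if (rng[1] == rng[2]) stop("constant matrix has no defined scale")
    out <- (m - rng[1]) / (rng[2] - rng[1])
    return(structure(out, source_tag = source_tag,
                     dropped_genes = character(0),
                     class = c("scaled_matrix", class(out))))
  }
  mins <- apply(m, 1, min)
  maxs <- apply(m, 1, max)
  constant <- maxs == mins
  dropped <- rownames(m)[constant]
  if (length(dropped) > 0)
    message(sprintf("minmax_scale: dropped %d constant genes",
                    length(dropped)))
  out <- (m[!constant, , drop = FALSE] - mins[!constant]) /
    (maxs[!constant] - mins[!constant])
  structure(out, source_tag = source_tag, dropped_genes = dropped,
            class = c("scaled_matrix", class(out)))
}

#' Run the full preprocessing pipeline on a paired-omics bundle
#'
#' Expression: low-CPM filter, FPKM-UQ normalization. Copy number: all-NA
#' removal and per-gene mean imputation. Both: restriction to shared genes
#' and patients (three-way intersection with the clinical table), then
#' per-gene min-max scaling to \[0, 1\]. Constant genes dropped at the
#' scaling stage are removed from *both* matrices so the matched gene sets
#' stay identical. Dimensions are logged at every step.
#'
#' @param bundle an `omics_bundle`.
#' @param min_cpm,min_samples low-expression filter parameters.
#' @return an object of class `preprocessed_omics`: list with `expr` and
#'   `cna` (scaled matrices over identical genes/patients), `clinical`
#'   (aligned to the shared patients), and `log` (dimension bookkeeping).
#' @export
preprocess_bundle <- function(bundle, min_cpm = 1, min_samples = 3) {
  log <- list(counts_in = dim(bundle$counts), cna_in = dim(bundle$cna_log2))
  keep <- filter_low_expression(bundle$counts, min_cpm, min_samples)
  counts <- bundle$counts[keep, , drop = FALSE]
  log$after_filter <- dim(counts)
  expr <- fpkm_uq(counts, bundle$gene_lengths)
  cna <- clean_cna(bundle$cna_log2)
  log$after_cna_clean <- dim(cna)
  matched <- match_genes(expr, cna, bundle$clinical)
  log$after_match <- dim(matched$expr)
  se <- minmax_scale(matched$expr, "expression")
  sc <- minmax_scale(matched$cna, "cna")
  genes <- sort(intersect(rownames(se), rownames(sc)))
  se <- se[genes, , drop = FALSE]
  sc <- sc[genes, , drop = FALSE]
  attr(se, "source_tag") <- "expression"
  attr(sc, "source_tag") <- "cna"
  log$final <- dim(se)
  message(sprintf(
    "preprocess: expression %d -> %d genes (filter), matched %d genes x %d patients",
    log$counts_in[1], log$after_filter[1], log$final[1], log$final[2]))
  clinical <- bundle$clinical[match(colnames(se),
                                    bundle$clinical$patient_id), ,
                              drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(expr = se, cna = sc, clinical = clinical, log = log),
            class = "preprocessed_omics")
}

#' @export
print.preprocessed_omics <- function(x, ...) {
  cat("Preprocessed paired omics\n")
  cat(sprintf("  %d matched genes x %d patients, values in [0, 1]\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}
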