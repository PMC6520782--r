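#' Trace feature-level Cox coefficients back to gene-level weights
#'
#' For a one-input model, the gene-level score is the matrix-vector
#' product `w_g = W B`: each gene's encode weights across the features,
#' weighted by the features' Cox coefficients.
#'
#' @param W genes x features encode weight matrix (with gene row names).
#' @param B length-features vector of Cox coefficients.
#' @param source_tag label recorded on the result.
#' @return named numeric vector of per-gene weights (class
#'   `gene_weights`), with attribute `source_tag`.
#' @export
trace_one_input <- function(W, B, source_tag = "expression") {
  W <- as.matrix(W)
  if (ncol(W) != length(B))
    stop("dimension mismatch: W has ", ncol(W), " columns, B has length ",
         length(B))
  w_g <- drop(W %*% B)
  names(w_g) <- rownames(W)
  structure(w_g, source_tag = source_tag, class = "gene_weights")
}

#' Gene-level trace-back for the two-input model
#'
#' The feature layer sees the two sources through the composition of the
#' per-source first-layer weights with the matching half of the second
#' layer: `composite_a = W1_a %*% W2[1:hidden1, ]` (genes x features), and
#' likewise for source b. Each composite is contracted with the Cox
#' coefficient vector as in [trace_one_input()]. For genes present in both
#' sources a combined score is also returned: the sum of the two per-source
#' scores by default, or the larger in magnitude with
#' `combine = "max_abs"`.
#'
#' @param W1_a,W1_b genes x hidden1 first-layer weights (gene row names).
#' @param W2 (2*hidden1) x features second-layer weights; rows 1..hidden1
#'   belong to source a.
#' @param B length-features vector of Cox coefficients.
#' @param combine how shared genes' two scores are merged: `"sum"`
#'   (default) or `"max_abs"`.
#' @return list with `a`, `b` (per-source `gene_weights`) and `combined`
#'   (over the shared genes).
#' @export
trace_two_input <- function(W1_a, W1_b, W2, B, combine = c("sum",
                                                           "max_abs")) {
  combine <- match.arg(combine)
  W1_a <- as.matrix(W1_a)
  W1_b <- as.matrix(W1_b)
  W2 <- as.matrix(W2)
  h1 <- ncol(W1_a)
  if (ncol(W1_b) != h1 || nrow(W2) != 2 * h1)
    stop("dimension mismatch: W2 must have 2 * ncol(W1_a) rows")
  if (ncol(W2) != length(B))
    stop("dimension mismatch: W2 has ", ncol(W2), " columns, B has length ",
         length(B))
  comp_a <- W1_a %*% W2[seq_len(h1), , drop = FALSE]
  comp_b <- W1_b %*% W2[h1 + seq_len(h1), , drop = FALSE]
  wa <- trace_one_input(comp_a, B, "concatenated:expression-side")
  wb <- trace_one_input(comp_b, B, "concatenated:cna-side")
  shared <- intersect(names(wa), names(wb))
  combined <- if (length(shared) > 0) {
    if (combine == "sum") wa[shared] + wb[shared]
    else ifelse(abs(wa[shared]) >= abs(wb[shared]), wa[shared],
                wb[shared])
  } else numeric(0)
  combined <- structure(unclass(combined), names = shared,
                        source_tag = "concatenated",
                        class = "gene_weights")
  list(a = wa, b = wb, combined = combined)
}

#' Filter gene weights by magnitude and rank them
#'
#' Keeps genes with `|w_g| >= cutoff`, ordered by decreasing `|w_g|` with
#' ties broken by gene identifier.
#'
#' @param gwv a `gene_weights` vector (named).
#' @param cutoff non-negative magnitude threshold (default 0.01).
#' @return object of class `gene_list`: data frame with `gene_id`, `w_g`,
#'   and attribute `cutoff`.
#' @export
filter_genes <- function(gwv, cutoff = 0.01) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  w <- as.numeric(gwv)
  names(w) <- names(gwv)
  keep <- abs(w) >= cutoff
  if (!any(keep)) warning("no genes pass the cutoff; empty list")
  w <- w[keep]
  ord <- order(-abs(w), names(w))
  out <- data.frame(gene_id = names(w)[ord], w_g = unname(w[ord]),
                    stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff,
            source_tag = attr(gwv, "source_tag"),
            class = c("gene_list", "data.frame"))
}

#' Export a ranked gene list for external enrichment tools
#'
#' Writes the plain list (one gene identifier per line) and, optionally, a
#' ranked two-column (gene, weight) tab-separated variant.
#'
#' @param gene_list a `gene_list` from [filter_genes()].
#' @param path output path for the one-per-line list.
#' @param ranked_path optional path for the two-column ranked file.
#' @return invisibly, `path`.
#' @export
export_gene_list <- function(gene_list, path, ranked_path = NULL) {
  if (nrow(gene_list) == 0) {
    writeLines(sprintf("# empty gene list (cutoff %g)",
                       attr(gene_list, "cutoff")), path)
  } else {
    writeLines(gene_list$gene_id, path)
  }
  if (!is.null(ranked_path)) {
    utils::write.table(as.data.frame(gene_list)[, c("gene_id", "w_g")],
                       ranked_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
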