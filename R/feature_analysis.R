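#' Hierarchical clustering of patients on feature activities
#'
#' Agglomerative clustering of the patients (rows of the activity matrix)
#' with complete linkage by default, cut into exactly `k` groups.
#'
#' @param features patients x features activity matrix (e.g.
#'   `fitted(dae_fit)`).
#' @param k number of groups (default 2).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @param metric distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return object of class `cluster_assignment`: list with `labels` (named
#'   integer vector in 1..k), `k`, `linkage`, `metric`, and `tree` (the
#'   `hclust` object, merge heights included).
#' @export
hier_cluster <- function(features, k = 2, linkage = "complete",
                         metric = "euclidean") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2 || k > n)
    stop("invalid config: k must be between 2 and the number of patients")
  tree <- stats::hclust(stats::dist(features, method = metric),
                        method = linkage)
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(features)
  structure(list(labels = labels, k = k, linkage = linkage,
                 metric = metric, tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage, %s distance), k = %d\n",
              x$linkage, x$metric, x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cluster-by-characteristic contingency table
#'
#' Counts patients per (cluster, category) cell; patients with a missing
#' value for the characteristic are excluded and their number recorded in
#' the `n_excluded` attribute.
#'
#' @param clusters a `cluster_assignment` (or a named label vector).
#' @param values per-patient categorical values, aligned with the labels
#'   (named, or in the same order).
#' @return an r x c contingency table of counts.
#' @export
contingency <- function(clusters, values) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  if (!is.null(names(labels)) && !is.null(names(values)))
    values <- values[names(labels)]
  stopifnot(length(values) == length(labels))
  ok <- !is.na(values)
  if (sum(ok) == 0) stop("no patients with a non-missing value")
  n_exc <- sum(!ok)
  if (n_exc > 0)
    message(sprintf("contingency: excluded %d patients with missing values",
                    n_exc))
  tab <- table(cluster = labels[ok], category = values[ok])
  attr(tab, "n_excluded") <- n_exc
  tab
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by the probability-ordering rule (summing hypergeometric
#' probabilities of all tables with the same margins that are no more
#' probable than the observed one). The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)`, reported as `NA` (undefined) when `b*c = 0`.
#'
#' @param tab 2x2 matrix/table of non-negative integer counts.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_exact expects a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  p <- stats::fisher.test(tab)$p.value
  or <- if (tab[1, 2] * tab[2, 1] == 0) NA_real_
        else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p_value = min(p, 1), odds_ratio = or)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic against the chi-square distribution with
#' `(r-1)(c-1)` degrees of freedom, no continuity correction. Rows or
#' columns with a zero margin are dropped with a warning; expected counts
#' below 5 trigger a message.
#'
#' @param tab r x c table of counts with a positive grand total.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
chisq_test <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) <= 0) stop("table must have a positive grand total")
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin rows/columns from the chi-square table")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = 0, df = 0, p_value = 1))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5))
    message("chisq_test: some expected counts are below 5")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Association tests between patient clusters and clinical characteristics
#'
#' For each characteristic, builds the cluster-by-category contingency
#' table (missing values excluded) and reports both the Fisher exact and
#' Pearson chi-square p-values, plus the sample odds ratio when the table
#' is 2x2.
#'
#' @param clusters a `cluster_assignment`.
#' @param clinical clinical data frame with a `patient_id` column matching
#'   the cluster label names.
#' @param fields characteristics to test (default: the standard clinical
#'   panel present in the table).
#' @param bh also report Benjamini-Hochberg adjusted Fisher p-values?
#' @return data frame with columns `characteristic`, `fisher_p`,
#'   `chisq_p`, `odds_ratio` (and `fisher_p_bh` when `bh = TRUE`).
#' @export
association_table <- function(clusters, clinical, fields = NULL,
                              bh = FALSE) {
  default_fields <- c("path_T", "path_N", "path_M", "stage", "er_status",
                      "pr_status", "her2_status", "age_group",
                      "triple_negative", "subtype")
  if (is.null(fields)) fields <- intersect(default_fields,
                                           colnames(clinical))
  labels <- clusters$labels
  rows <- lapply(fields, function(f) {
    vals <- stats::setNames(clinical[[f]], clinical$patient_id)
    tab <- suppressMessages(contingency(labels, vals))
    fp <- if (nrow(tab) < 2 || ncol(tab) < 2) 1 else tryCatch(
      stats::fisher.test(tab, workspace = 2e6)$p.value,
      error = function(e)
        stats::fisher.test(tab, simulate.p.value = TRUE,
                           B = 1e4)$p.value)
    or <- if (all(dim(tab) == c(2, 2))) fisher_exact(tab)$odds_ratio
          else NA_real_
    cp <- suppressMessages(chisq_test(tab)$p_value)
    data.frame(characteristic = f, fisher_p = min(fp, 1), chisq_p = cp,
               odds_ratio = or, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$fisher_p_bh <- stats::p.adjust(out$fisher_p, "BH")
  rownames(out) <- NULL
  out
}

#' Export a cluster-ordered activity heat map
#'
#' Reorders the activity matrix by the patient and feature dendrograms,
#' writes the ordered matrix as tab-separated text (so any plot can be
#' reproduced from it), and optionally renders a heat map with clinical
#' side-bar annotations.
#'
#' @param features patients x features activity matrix.
#' @param clusters a `cluster_assignment` over the same patients.
#' @param clinical optional clinical data frame (`patient_id` plus
#'   categorical columns) used for the side-bar tracks.
#' @param matrix_file path for the ordered matrix TSV.
#' @param plot_file optional path for a PNG heat map.
#' @param annotation_fields clinical columns to use as side bars.
#' @return invisibly, the ordered (features x patients) matrix.
#' @export
heatmap_export <- function(features, clusters, clinical = NULL,
                           matrix_file, plot_file = NULL,
                           annotation_fields = c("er_status", "pr_status",
                                                 "her2_status", "stage",
                                                 "subtype")) {
  features <- as.matrix(features)
  patient_order <- clusters$tree$order
  feat_tree <- stats::hclust(stats::dist(t(features)),
                             method = clusters$linkage)
  ordered <- t(features)[feat_tree$order, patient_order, drop = FALSE]
  write_matrix_tsv(ordered, matrix_file, id_col = "feature_id")
  if (!is.null(plot_file)) {
    ann <- NA
    if (!is.null(clinical)) {
      fields <- intersect(annotation_fields, colnames(clinical))
      ann <- clinical[match(colnames(ordered), clinical$patient_id),
                      fields, drop = FALSE]
      ann$cluster <- factor(clusters$labels[colnames(ordered)])
      rownames(ann) <- colnames(ordered)
    }
    grDevices::png(plot_file, width = 1000, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    pheatmap::pheatmap(ordered, cluster_rows = FALSE, cluster_cols = FALSE,
                       annotation_col = ann, show_colnames = FALSE,
                       main = "Deep feature activities")
  }
  invisible(ordered)
}
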