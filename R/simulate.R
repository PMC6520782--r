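#' Simulation configuration for paired-omics bundles
#'
#' Bundles the knobs of the synthetic paired-omics generator. The generator
#' plants `n_latent` latent factors shared by the expression and copy-number
#' matrices; the first factor carries a two-group mean shift of size
#' `group_effect` and drives the survival hazard through `hazard_coef`, so a
#' known subgroup structure, an ER-like binary label, and a survival signal
#' are all recoverable downstream.
#'
#' @param n_patients number of patients (columns of both omics matrices).
#' @param n_genes number of genes in the shared gene pool.
#' @param n_latent number of latent factors; each loads on a disjoint gene
#'   block.
#' @param group_effect non-negative separation between the two planted
#'   subgroups along latent factor 1 (standard-deviation units).
#' @param hazard_coef log-hazard-ratio linking latent factor 1 to overall
#'   survival.
#' @param censor_rate target fraction of right-censored patients, in
#'   \[0, 1\].
#' @param er_flip_prob probability that the ER-like label disagrees with the
#'   planted group label, in \[0, 0.5\].
#' @param frac_source_specific fraction of the gene pool present in only one
#'   omics source (split evenly), so cross-omics gene matching is exercised.
#' @param nb_dispersion negative-binomial dispersion of the counts
#'   (`size = 1/nb_dispersion`).
#' @param seed integer RNG seed; the whole bundle is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 300, n_genes = 2000, n_latent = 3,
                       group_effect = 3, hazard_coef = 0.8,
                       censor_rate = 0.3, er_flip_prob = 0.1,
                       frac_source_specific = 0.1, nb_dispersion = 0.2,
                       seed = 1) {
  stopifnot(length(n_patients) == 1, length(n_genes) == 1,
            length(n_latent) == 1)
  if (n_patients < 1 || n_genes < 1 || n_latent < 1 ||
      n_patients != round(n_patients) || n_genes != round(n_genes))
    stop("invalid config: dimensions must be positive integers")
  if (n_latent >= n_genes || n_latent >= n_patients)
    stop("invalid config: n_latent must be smaller than n_genes and n_patients")
  if (censor_rate < 0 || censor_rate > 1)
    stop("invalid config: censor_rate must be in [0, 1]")
  if (er_flip_prob < 0 || er_flip_prob > 0.5)
    stop("invalid config: er_flip_prob must be in [0, 0.5]")
  if (group_effect < 0)
    stop("invalid config: group_effect must be non-negative")
  if (frac_source_specific < 0 || frac_source_specific >= 1)
    stop("invalid config: frac_source_specific must be in [0, 1)")
  if (nb_dispersion <= 0)
    stop("invalid config: nb_dispersion must be positive")
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 n_latent = as.integer(n_latent),
                 group_effect = group_effect, hazard_coef = hazard_coef,
                 censor_rate = censor_rate, er_flip_prob = er_flip_prob,
                 frac_source_specific = frac_source_specific,
                 nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Solve for the uniform-censoring horizon c_max such that the expected
# censoring fraction over patients with exponential event rates `rates`
# matches `target`. With C ~ U(0, cmax), P(censored) = P(T > C) =
# (1 - exp(-rate*cmax)) / (rate*cmax), decreasing in cmax.
.censor_horizon <- function(rates, target) {
  f <- function(cmax) {
    mean((1 - exp(-rates * cmax)) / (rates * cmax)) - target
  }
  lo <- 1e-8 / mean(rates)
  hi <- 1e8 / mean(rates)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a paired-omics bundle with planted latent structure
#'
#' Draws RNA-seq-like counts (negative binomial, log-mean linear in the
#' latent factors through a block-sparse loading matrix), gene-level log2
#' copy-number values driven by the *same* latent factors plus Gaussian
#' noise, right-censored exponential survival whose hazard depends on latent
#' factor 1, and an ER-like binary label correlated with the planted group.
#' A configurable fraction of genes appears in only one omics source so that
#' cross-omics gene matching is non-trivial.
#'
#' @param config a [sim_config()].
#' @return an object of class `omics_bundle`: a list with elements `counts`
#'   (genes x patients integer matrix), `gene_lengths` (named positive
#'   integers, bases), `cna_log2` (genes x patients real matrix), `clinical`
#'   (data frame, one row per patient), and `truth` (list with
#'   `group_label`, `latent_factors`, `causal_genes`).
#' @examples
#' b <- simulate_bundle(sim_config(n_patients = 50, n_genes = 200, seed = 1))
#' dim(b$counts)
#' @export
simulate_bundle <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_patients
  g <- config$n_genes
  q <- config$n_latent

  gene_ids <- sprintf("G%05d", seq_len(g))
  patient_ids <- sprintf("P%04d", seq_len(n))

  ## planted subgroups and latent factors; factor 1 carries the group shift
  group <- stats::rbinom(n, 1, 0.5)
  Z <- matrix(stats::rnorm(n * q), n, q,
              dimnames = list(patient_ids, paste0("LF", seq_len(q))))
  Z[, 1] <- Z[, 1] + (group - 0.5) * config$group_effect

  ## block-sparse loadings: each factor loads on a disjoint gene block
  block_size <- max(1L, floor(0.6 * g / q))
  L_expr <- matrix(0, g, q)
  L_cna <- matrix(0, g, q)
  blocks <- vector("list", q)
  for (j in seq_len(q)) {
    idx <- ((j - 1L) * block_size + 1L):(j * block_size)
    blocks[[j]] <- idx
    signs <- sample(c(-1, 1), length(idx), replace = TRUE)
    L_expr[idx, j] <- signs * stats::runif(length(idx), 0.5, 1.2)
    L_cna[idx, j] <- signs * stats::runif(length(idx), 0.5, 1.2)
  }
  causal_genes <- gene_ids[blocks[[1]]]

  ## counts: NB with log-mean = baseline + loadings %*% factors; a small
  ## tail of near-silent genes exercises the low-expression filter
  baseline <- stats::rnorm(g, mean = log(80), sd = 1.5)
  n_silent <- max(1L, round(0.05 * g))
  silent <- sample(setdiff(seq_len(g), blocks[[1]]), n_silent)
  baseline[silent] <- log(0.02)
  mu <- exp(baseline + L_expr %*% t(Z))
  counts <- matrix(stats::rnbinom(g * n, size = 1 / config$nb_dispersion,
                                  mu = mu),
                   g, n, dimnames = list(gene_ids, patient_ids))

  gene_lengths <- sample(200:10000, g, replace = TRUE)
  names(gene_lengths) <- gene_ids

  ## CNA on a log2-ratio scale, same factors, independent noise
  cna <- 0.4 * (L_cna %*% t(Z)) +
    matrix(stats::rnorm(g * n, sd = 0.3), g, n)
  dimnames(cna) <- list(gene_ids, patient_ids)

  ## source-specific genes: drop disjoint non-causal sets from each matrix
  n_drop <- round(config$frac_source_specific / 2 * g)
  if (n_drop > 0) {
    droppable <- setdiff(seq_len(g), blocks[[1]])
    drop_both <- sample(droppable, 2L * n_drop)
    counts <- counts[-drop_both[seq_len(n_drop)], , drop = FALSE]
    cna <- cna[-drop_both[n_drop + seq_len(n_drop)], , drop = FALSE]
    gene_lengths <- gene_lengths[rownames(counts)]
  }

  ## survival: exponential with baseline hazard 1/1000 per day
  h0 <- 1 / 1000
  rates <- h0 * exp(config$hazard_coef * Z[, 1])
  t_event <- stats::rexp(n, rates)
  if (config$censor_rate <= 0) {
    os_time <- t_event
    os_event <- rep(1L, n)
  } else {
    cmax <- .censor_horizon(rates, config$censor_rate)
    c_time <- stats::runif(n, 0, cmax)
    os_event <- as.integer(t_event <= c_time)
    os_time <- pmin(t_event, c_time)
  }

  ## ER-like label tied to the planted group; group 1 (higher factor-1,
  ## higher hazard when hazard_coef > 0) maps to ER-negative
  flip <- stats::rbinom(n, 1, config$er_flip_prob)
  er <- ifelse(xor(group == 1, flip == 1), "Negative", "Positive")

  age <- round(stats::rnorm(n, 58, 12))
  clinical <- data.frame(
    patient_id = patient_ids,
    os_time = os_time,
    os_event = os_event,
    er_status = er,
    pr_status = sample(c("Positive", "Negative", NA), n, replace = TRUE,
                       prob = c(0.55, 0.4, 0.05)),
    her2_status = sample(c("Positive", "Negative", NA), n, replace = TRUE,
                         prob = c(0.2, 0.75, 0.05)),
    triple_negative = sample(c("Yes", "No"), n, replace = TRUE,
                             prob = c(0.15, 0.85)),
    path_T = sample(paste0("T", 1:4), n, replace = TRUE,
                    prob = c(0.25, 0.5, 0.15, 0.1)),
    path_N = sample(paste0("N", 0:3), n, replace = TRUE,
                    prob = c(0.45, 0.35, 0.12, 0.08)),
    path_M = sample(paste0("M", 0:1), n, replace = TRUE,
                    prob = c(0.97, 0.03)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.18, 0.55, 0.22, 0.05)),
    subtype = sample(c("LumA", "LumB", "Basal", "Her2", "Normal"), n,
                     replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.1, 0.1)),
    age_group = ifelse(age < 40, "young", "old"),
    stringsAsFactors = FALSE
  )

  structure(list(counts = counts, gene_lengths = gene_lengths,
                 cna_log2 = cna, clinical = clinical,
                 truth = list(group_label = stats::setNames(group,
                                                            patient_ids),
                              latent_factors = Z,
                              causal_genes = causal_genes),
                 config = config),
            class = "omics_bundle")
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat("Paired omics bundle\n")
  cat(sprintf("  counts:   %d genes x %d patients\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  cna_log2: %d genes x %d patients\n",
              nrow(x$cna_log2), ncol(x$cna_log2)))
  cat(sprintf("  clinical: %d patients, %d fields\n",
              nrow(x$clinical), ncol(x$clinical)))
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: %d latent factors, %d causal genes\n",
                ncol(x$truth$latent_factors), length(x$truth$causal_genes)))
  invisible(x)
}

#' Write a bundle's components as tab-separated text files
#'
#' Matrices are written one row per gene with patient identifiers as column
#' headers; clinical and ground-truth tables one row per patient.
#'
#' @param bundle an `omics_bundle`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"),
             cna = file.path(dir, "cna_log2.tsv"),
             clinical = file.path(dir, "clinical.tsv"))
  write_matrix_tsv(bundle$counts, paths["counts"])
  utils::write.table(data.frame(gene_id = names(bundle$gene_lengths),
                                length = as.integer(bundle$gene_lengths)),
                     paths["lengths"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(bundle$cna_log2, paths["cna"])
  utils::write.table(bundle$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth)) {
    paths <- c(paths, truth = file.path(dir, "ground_truth.tsv"),
               causal = file.path(dir, "causal_genes.txt"))
    tr <- data.frame(patient_id = names(bundle$truth$group_label),
                     group_label = as.integer(bundle$truth$group_label),
                     bundle$truth$latent_factors,
                     check.names = FALSE)
    utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(bundle$truth$causal_genes, paths["causal"])
  }
  invisible(paths)
}

#' Read a bundle previously written by [write_bundle()]
#'
#' @param dir directory containing the tab-separated components.
#' @return an `omics_bundle` (with `truth` when the ground-truth files are
#'   present).
#' @export
read_bundle <- function(dir) {
  counts <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  storage.mode(counts) <- "integer"
  lengths_df <- utils::read.delim(file.path(dir, "gene_lengths.tsv"))
  gene_lengths <- stats::setNames(lengths_df$length, lengths_df$gene_id)
  cna <- read_matrix_tsv(file.path(dir, "cna_log2.tsv"))
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  truth <- NULL
  tp <- file.path(dir, "ground_truth.tsv")
  if (file.exists(tp)) {
    tr <- utils::read.delim(tp, check.names = FALSE)
    Z <- as.matrix(tr[, -(1:2), drop = FALSE])
    rownames(Z) <- tr$patient_id
    truth <- list(group_label = stats::setNames(tr$group_label,
                                                tr$patient_id),
                  latent_factors = Z,
                  causal_genes = readLines(file.path(dir,
                                                     "causal_genes.txt")))
  }
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 cna_log2 = cna, clinical = clinical, truth = truth),
            class = "omics_bundle")
}
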