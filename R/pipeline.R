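.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(stage)) %% 2147483647)
}

#' Pipeline configuration
#'
#' Collects every stage's settings with defaults matching the method's
#' standard configuration: corruption noise 0.25, SGD learning rate 0.1,
#' batch size 64, 100 epochs, dropout 0.5, 100 features (1000-wide
#' per-source first encodes for the two-input model), k = 2 patient
#' clusters, 0.55 risk-score quantile, 0.01 gene-weight cutoff.
#'
#' @param sim optional [sim_config()]; when given, the pipeline simulates
#'   its input bundle.
#' @param input_dir directory with a bundle written by [write_bundle()]
#'   (used when `sim` is `NULL`).
#' @param hidden,hidden1 autoencoder widths.
#' @param noise_factor,learning_rate,batch_size,epochs,dropout_rate
#'   training settings (see [dae()]).
#' @param k number of patient clusters.
#' @param prob risk-score binarization quantile.
#' @param cutoff gene-weight magnitude cutoff.
#' @param min_cpm,min_samples low-expression filter settings.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param make_plots write PNG heat map and KM plots?
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, hidden = 100,
                            hidden1 = 1000, noise_factor = 0.25,
                            learning_rate = 0.1, batch_size = 64,
                            epochs = 100, dropout_rate = 0.5, k = 2,
                            prob = 0.55, cutoff = 0.01, min_cpm = 1,
                            min_samples = 3, seed = 1,
                            make_plots = FALSE) {
  if (is.null(sim) && is.null(input_dir))
    stop("either a simulation config or an input directory is required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or bundle loading), preprocessing, the
#' three autoencoder fits (expression, copy number, two-input
#' concatenated), patient clustering and clinical association testing for
#' each feature set, per-feature Cox fits, risk scoring, quantile
#' binarization and survival evaluation, and gene-level trace-back with
#' filtered ranked gene-list export. Every artifact is written under
#' `outdir` as tab-separated text, and a machine-readable `summary.json`
#' collects the association and hazard-ratio reports.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = config$seed)

  stage <- "simulate/load"
  bundle <- tryCatch({
    if (!is.null(config$sim)) {
      b <- simulate_bundle(config$sim)
      write_bundle(b, file.path(outdir, "bundle"))
      b
    } else read_bundle(config$input_dir)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e)))

  stage <- "preprocess"
  pp <- tryCatch(
    suppressMessages(preprocess_bundle(bundle, config$min_cpm,
                                       config$min_samples)),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  summary$dimensions <- pp$log
  message(sprintf("[preprocess] %d genes x %d patients after matching",
                  nrow(pp$expr), ncol(pp$expr)))

  stage <- "train"
  fits <- tryCatch(list(
    expression = dae(pp$expr, hidden = config$hidden,
                     noise_factor = config$noise_factor,
                     learning_rate = config$learning_rate,
                     batch_size = config$batch_size,
                     epochs = config$epochs,
                     dropout_rate = config$dropout_rate,
                     seed = .stage_seed(config$seed, 1)),
    cna = dae(pp$cna, hidden = config$hidden,
              noise_factor = config$noise_factor,
              learning_rate = config$learning_rate,
              batch_size = config$batch_size, epochs = config$epochs,
              dropout_rate = config$dropout_rate,
              seed = .stage_seed(config$seed, 2)),
    concatenated = dae(list(pp$expr, pp$cna), hidden = config$hidden,
                       hidden1 = config$hidden1,
                       noise_factor = config$noise_factor,
                       learning_rate = config$learning_rate,
                       batch_size = config$batch_size,
                       epochs = config$epochs,
                       dropout_rate = config$dropout_rate,
                       seed = .stage_seed(config$seed, 3))),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  summary$final_loss <- lapply(fits, function(f)
    if (length(f$loss_history) > 0) utils::tail(f$loss_history, 1)
    else NA)

  clinical <- pp$clinical
  times <- clinical$os_time
  events <- clinical$os_event

  for (nm in names(fits)) {
    fit <- fits[[nm]]
    act <- fitted(fit)
    write_matrix_tsv(act, file.path(outdir,
                                    sprintf("features_%s.tsv", nm)),
                     id_col = "patient_id")
    save_dae(fit, file.path(outdir, sprintf("model_%s", nm)))

    stage <- paste0("cluster:", nm)
    cl <- tryCatch(hier_cluster(act, k = config$k),
                   error = function(e) stop("stage '", stage,
                                            "' failed: ",
                                            conditionMessage(e)))
    utils::write.table(
      data.frame(patient_id = names(cl$labels), cluster = cl$labels),
      file.path(outdir, sprintf("clusters_%s.tsv", nm)), sep = "\t",
      quote = FALSE, row.names = FALSE)

    stage <- paste0("associate:", nm)
    assoc <- tryCatch(suppressMessages(
      association_table(cl, clinical)),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e)))
    utils::write.table(assoc,
                       file.path(outdir,
                                 sprintf("associations_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ckm <- km_estimate(times, events, cl$labels)
    summary[[paste0("associations_", nm)]] <- assoc
    summary[[paste0("cluster_logrank_p_", nm)]] <- ckm$p_value

    heatmap_export(act, cl, clinical,
                   matrix_file = file.path(outdir,
                                           sprintf("heatmap_%s.tsv", nm)),
                   plot_file = if (config$make_plots)
                     file.path(outdir, sprintf("heatmap_%s.png", nm))
                   else NULL)

    stage <- paste0("risk:", nm)
    ct <- tryCatch(cox_feature_table(act, times, events),
                   error = function(e) stop("stage '", stage,
                                            "' failed: ",
                                            conditionMessage(e)))
    utils::write.table(ct, file.path(outdir, sprintf("cox_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scores <- risk_score(act, ct)
    profile <- binarize_risk(scores, prob = config$prob,
                             coefficients = ct$b)
    utils::write.table(
      data.frame(patient_id = names(profile$group),
                 score = profile$scores, group = profile$group),
      file.path(outdir, sprintf("risk_%s.tsv", nm)), sep = "\t",
      quote = FALSE, row.names = FALSE)
    ev <- evaluate_risk_groups(profile, times, events)
    summary[[paste0("risk_report_", nm)]] <- ev$report

    stage <- paste0("traceback:", nm)
    if (fit$kind == "one") {
      W <- fit$params$W
      rownames(W) <- fit$gene_ids
      gw <- trace_one_input(W, ct$b, source_tag = nm)
      gl <- filter_genes(gw, config$cutoff)
      export_gene_list(gl,
                       file.path(outdir, sprintf("genes_%s.txt", nm)),
                       file.path(outdir,
                                 sprintf("genes_%s_ranked.tsv", nm)))
      summary[[paste0("gene_list_size_", nm)]] <- nrow(gl)
    } else {
      W1a <- fit$params$W1_a
      rownames(W1a) <- fit$gene_ids$a
      W1b <- fit$params$W1_b
      rownames(W1b) <- fit$gene_ids$b
      tw <- trace_two_input(W1a, W1b, fit$params$W2, ct$b)
      gl <- filter_genes(tw$combined, config$cutoff)
      export_gene_list(gl,
                       file.path(outdir, sprintf("genes_%s.txt", nm)),
                       file.path(outdir,
                                 sprintf("genes_%s_ranked.tsv", nm)))
      summary[[paste0("gene_list_size_", nm)]] <- nrow(gl)
    }
    message(sprintf("[%s] cluster log-rank p = %.3g, risk HR = %.3f",
                    nm, ckm$p_value, ev$report$hr))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       null = "null", na = "null")
  invisible(summary)
}
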