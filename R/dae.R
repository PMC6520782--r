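#' Numerically stable logistic function
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, evaluated without overflow for large
#' `|x|` and clamped to the open interval (0, 1) so downstream logs are
#' finite.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with entries strictly in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  pmin(pmax(out, 1e-300), 1 - 1e-16)
}

#' Masking corruption of a scaled input matrix
#'
#' The denoising corruption: for each patient column independently, exactly
#' `round(noise_factor * n_genes)` gene positions are drawn without
#' replacement and set to 0. With `unit = "gene"` a single set of whole gene
#' rows is zeroed instead (same genes for every patient).
#'
#' @param x genes x patients matrix in \[0, 1\].
#' @param noise_factor fraction of genes to zero, in \[0, 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param unit `"column"` (per-patient sampling, the default) or `"gene"`
#'   (whole rows).
#' @return list with `values` (corrupted matrix) and `mask` (logical matrix,
#'   `TRUE` where zeroed).
#' @export
corrupt <- function(x, noise_factor = 0.25, seed = NULL,
                    unit = c("column", "gene")) {
  unit <- match.arg(unit)
  if (noise_factor < 0 || noise_factor >= 1)
    stop("invalid config: noise_factor must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  g <- nrow(x)
  n <- ncol(x)
  mask <- matrix(FALSE, g, n, dimnames = dimnames(x))
  k <- round(noise_factor * g)
  if (k > 0) {
    if (unit == "column") {
      for (j in seq_len(n)) mask[sample.int(g, k), j] <- TRUE
    } else {
      mask[sample.int(g, k), ] <- TRUE
    }
  }
  values <- x
  values[mask] <- 0
  list(values = values, mask = mask)
}

#' Binary cross-entropy between a clean target and a reconstruction
#'
#' Mean over all entries of `-(t*log(o) + (1-t)*log(1-o))`. Outputs lying
#' exactly on 0 or 1 are clamped by a small epsilon (and reported), so the
#' loss stays finite.
#'
#' @param target matrix or vector with entries in \[0, 1\].
#' @param output matrix or vector of the same shape with entries in (0, 1).
#' @return non-negative scalar.
#' @export
bce_loss <- function(target, output) {
  stopifnot(length(target) == length(output))
  if (any(target < 0 | target > 1)) stop("target entries must be in [0, 1]")
  if (any(output <= 0 | output >= 1)) {
    message("bce_loss: clamping boundary outputs by epsilon")
    output <- pmin(pmax(output, 1e-12), 1 - 1e-12)
  }
  -mean(target * log(output) + (1 - target) * log(1 - output))
}

## Glorot-style symmetric uniform initialization, seeded by the caller.
.glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

.init_one <- function(input_dim, hidden) {
  list(W = .glorot(input_dim, hidden),
       b = numeric(hidden),
       b_dec = numeric(input_dim))
}

.init_two <- function(dim_a, dim_b, hidden1, hidden) {
  list(W1_a = .glorot(dim_a, hidden1), W1_b = .glorot(dim_b, hidden1),
       b1_a = numeric(hidden1), b1_b = numeric(hidden1),
       W2 = .glorot(2 * hidden1, hidden), b2 = numeric(hidden),
       b_dec_a = numeric(dim_a), b_dec_b = numeric(dim_b),
       b_dec_mid = numeric(2 * hidden1))
}

.dropout_mask <- function(h, n, rate) {
  matrix(stats::runif(h * n) >= rate, h, n)
}

#' Forward pass of the one-input tied-weight autoencoder
#'
#' `encode = sigmoid(W' x + b)`; the decode layer reuses the transpose of
#' the encode weights: `reconstruction = sigmoid(W encode + b_dec)`. In
#' training mode, inverted dropout is applied after the encode layer (each
#' unit zeroed with probability `dropout_rate`, survivors scaled by
#' `1/(1 - dropout_rate)`); in inference mode dropout is the identity.
#'
#' @param params list with `W` (input_dim x hidden), `b` (hidden),
#'   `b_dec` (input_dim).
#' @param x input vector of length input_dim, or input_dim x n matrix.
#' @param train_mode apply dropout?
#' @param dropout_rate dropout probability (default 0.5).
#' @param dropout_seed optional seed for the dropout mask.
#' @return list with `encode` (hidden x n) and `reconstruction`
#'   (input_dim x n).
#' @export
forward_one <- function(params, x, train_mode = FALSE, dropout_rate = 0.5,
                        dropout_seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(params$W))
    stop("dimension mismatch: input has ", nrow(x), " rows, W expects ",
         nrow(params$W))
  h <- sigmoid(crossprod(params$W, x) + params$b)
  hd <- h
  if (train_mode && dropout_rate > 0) {
    if (!is.null(dropout_seed)) set.seed(dropout_seed)
    m <- .dropout_mask(nrow(h), ncol(h), dropout_rate)
    hd <- h * m / (1 - dropout_rate)
  }
  list(encode = h,
       reconstruction = sigmoid(params$W %*% hd + params$b_dec))
}

#' Forward pass of the two-input concatenated autoencoder
#'
#' Per-source first encodes (width `hidden1` each) are concatenated and
#' passed through a second encode layer (width `hidden`), whose output is
#' the concatenated feature vector. The decode path is fully tied: the
#' transpose of `W2` maps the features back to a 2*hidden1 mid layer, which
#' is split in half and decoded per source through the transposes of `W1_a`
#' and `W1_b`. Dropout (training mode only) acts on the second encode layer.
#'
#' @param params list with `W1_a`, `W1_b` (input_dim x hidden1), `b1_a`,
#'   `b1_b`, `W2` (2*hidden1 x hidden), `b2`, `b_dec_a`, `b_dec_b`,
#'   `b_dec_mid`.
#' @param x_a,x_b input vectors/matrices for the two sources (same number
#'   of columns).
#' @inheritParams forward_one
#' @return list with `encode2` (hidden x n), `recon_a`, `recon_b`.
#' @export
forward_two <- function(params, x_a, x_b, train_mode = FALSE,
                        dropout_rate = 0.5, dropout_seed = NULL) {
  x_a <- as.matrix(x_a)
  x_b <- as.matrix(x_b)
  if (ncol(x_a) != ncol(x_b))
    stop("dimension mismatch: the two inputs have different patient counts")
  if (nrow(x_a) != nrow(params$W1_a) || nrow(x_b) != nrow(params$W1_b))
    stop("dimension mismatch between inputs and first-layer weights")
  h1 <- ncol(params$W1_a)
  ha <- sigmoid(crossprod(params$W1_a, x_a) + params$b1_a)
  hb <- sigmoid(crossprod(params$W1_b, x_b) + params$b1_b)
  cc <- rbind(ha, hb)
  h2 <- sigmoid(crossprod(params$W2, cc) + params$b2)
  h2d <- h2
  if (train_mode && dropout_rate > 0) {
    if (!is.null(dropout_seed)) set.seed(dropout_seed)
    m <- .dropout_mask(nrow(h2), ncol(h2), dropout_rate)
    h2d <- h2 * m / (1 - dropout_rate)
  }
  mid <- sigmoid(params$W2 %*% h2d + params$b_dec_mid)
  ma <- mid[seq_len(h1), , drop = FALSE]
  mb <- mid[h1 + seq_len(h1), , drop = FALSE]
  list(encode2 = h2,
       recon_a = sigmoid(params$W1_a %*% ma + params$b_dec_a),
       recon_b = sigmoid(params$W1_b %*% mb + params$b_dec_b))
}

## Loss + analytic gradients of the one-input model on one mini-batch.
## `xc` is the corrupted input, `tgt` the clean target; `drop_mask` is a
## 0/1 matrix (NULL = no dropout). Tied weights: the W gradient sums the
## encode-path and decode-path contributions.
.fb_one <- function(params, xc, tgt, drop_mask = NULL, dropout_rate = 0.5) {
  d <- nrow(xc)
  n <- ncol(xc)
  h <- sigmoid(crossprod(params$W, xc) + params$b)
  hd <- if (is.null(drop_mask)) h else h * drop_mask / (1 - dropout_rate)
  o <- sigmoid(params$W %*% hd + params$b_dec)
  loss <- bce_loss(tgt, o)
  delta <- (o - tgt) / (d * n)
  gW <- delta %*% t(hd)
  g_bdec <- rowSums(delta)
  dh <- crossprod(params$W, delta)
  if (!is.null(drop_mask)) dh <- dh * drop_mask / (1 - dropout_rate)
  dh <- dh * h * (1 - h)
  gW <- gW + xc %*% t(dh)
  list(loss = loss, gW = gW, g_b = rowSums(dh), g_bdec = g_bdec)
}

## Loss + analytic gradients of the two-input model on one mini-batch.
.fb_two <- function(params, xa_c, xb_c, ta, tb, drop_mask = NULL,
                    dropout_rate = 0.5) {
  h1 <- ncol(params$W1_a)
  n <- ncol(xa_c)
  da <- nrow(xa_c)
  db <- nrow(xb_c)
  ha <- sigmoid(crossprod(params$W1_a, xa_c) + params$b1_a)
  hb <- sigmoid(crossprod(params$W1_b, xb_c) + params$b1_b)
  cc <- rbind(ha, hb)
  h2 <- sigmoid(crossprod(params$W2, cc) + params$b2)
  h2d <- if (is.null(drop_mask)) h2 else h2 * drop_mask / (1 - dropout_rate)
  mid <- sigmoid(params$W2 %*% h2d + params$b_dec_mid)
  ma <- mid[seq_len(h1), , drop = FALSE]
  mb <- mid[h1 + seq_len(h1), , drop = FALSE]
  oa <- sigmoid(params$W1_a %*% ma + params$b_dec_a)
  ob <- sigmoid(params$W1_b %*% mb + params$b_dec_b)
  loss <- bce_loss(ta, oa) + bce_loss(tb, ob)

  delta_a <- (oa - ta) / (da * n)
  delta_b <- (ob - tb) / (db * n)
  gW1a <- delta_a %*% t(ma)
  gW1b <- delta_b %*% t(mb)
  dma <- crossprod(params$W1_a, delta_a) * ma * (1 - ma)
  dmb <- crossprod(params$W1_b, delta_b) * mb * (1 - mb)
  dmid <- rbind(dma, dmb)
  gW2 <- dmid %*% t(h2d)
  dh2 <- crossprod(params$W2, dmid)
  if (!is.null(drop_mask)) dh2 <- dh2 * drop_mask / (1 - dropout_rate)
  dh2 <- dh2 * h2 * (1 - h2)
  gW2 <- gW2 + cc %*% t(dh2)
  dcc <- params$W2 %*% dh2
  dha <- dcc[seq_len(h1), , drop = FALSE] * ha * (1 - ha)
  dhb <- dcc[h1 + seq_len(h1), , drop = FALSE] * hb * (1 - hb)
  gW1a <- gW1a + xa_c %*% t(dha)
  gW1b <- gW1b + xb_c %*% t(dhb)
  list(loss = loss,
       gW1_a = gW1a, gW1_b = gW1b, gW2 = gW2,
       g_b1_a = rowSums(dha), g_b1_b = rowSums(dhb), g_b2 = rowSums(dh2),
       g_bdec_a = rowSums(delta_a), g_bdec_b = rowSums(delta_b),
       g_bdec_mid = rowSums(dmid))
}

.epoch_seed <- function(seed, epoch) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(epoch)) %% 2147483647)
}

#' Fit a denoising autoencoder to one or two scaled omics matrices
#'
#' The model-fitting entry point. Given a single genes x patients matrix in
#' \[0, 1\], fits the one-input tied-weight architecture (one encode layer of
#' `hidden` units whose sigmoid outputs are the feature activities). Given a
#' list of two matrices over the same patients, fits the two-input
#' architecture (per-source encodes of `hidden1` units, concatenated, then a
#' `hidden`-unit feature layer; tied decode path).
#'
#' Training is plain stochastic gradient descent on the mean binary
#' cross-entropy between the reconstruction and the *clean* input (the
#' denoising objective), with masking corruption of the input and inverted
#' dropout after the feature layer. Corruption is redrawn each epoch by
#' default (`corruption = "fixed"` keeps the first draw). Mini-batches are
#' reshuffled every epoch. The run is fully reproducible from `seed`.
#'
#' @param x genes x patients matrix in \[0, 1\], or a list of two such
#'   matrices (expression first) sharing patient columns.
#' @param hidden number of feature units (default 100).
#' @param hidden1 per-source first-encode width of the two-input model
#'   (default 1000).
#' @param noise_factor fraction of genes zeroed per patient (default 0.25).
#' @param learning_rate SGD step size (default 0.1).
#' @param batch_size mini-batch size over patients (default 64); when fewer
#'   patients are available a single batch is used.
#' @param epochs number of passes over the data (default 100); 0 returns
#'   the initialized model.
#' @param dropout_rate dropout probability on the feature layer (default
#'   0.5).
#' @param seed integer seed controlling initialization, corruption,
#'   shuffling and dropout.
#' @param corruption `"per_epoch"` (redraw the mask each epoch, default) or
#'   `"fixed"`.
#' @param corruption_unit passed to [corrupt()]: `"column"` or `"gene"`.
#' @return an object of class `dae` with components `kind` ("one" or
#'   "two"), `params`, `loss_history` (one mean BCE per epoch), `activity`
#'   (patients x hidden feature matrix computed on the clean input in
#'   inference mode, columns `F001`...), `config`, and the training input
#'   dimensions/identifiers.
#' @seealso [predict.dae()], [coef.dae()], [plot.dae()], [save_dae()]
#' @export
dae <- function(x, hidden = 100, hidden1 = 1000, noise_factor = 0.25,
                learning_rate = 0.1, batch_size = 64, epochs = 100,
                dropout_rate = 0.5, seed = 1,
                corruption = c("per_epoch", "fixed"),
                corruption_unit = c("column", "gene")) {
  corruption <- match.arg(corruption)
  corruption_unit <- match.arg(corruption_unit)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("invalid config: dropout_rate must be in [0, 1)")
  if (epochs < 0 || batch_size < 1)
    stop("invalid config: epochs must be >= 0 and batch_size >= 1")
  two <- is.list(x) && !is.data.frame(x)
  if (two) {
    stopifnot(length(x) == 2)
    xa <- as.matrix(x[[1]])
    xb <- as.matrix(x[[2]])
    if (ncol(xa) != ncol(xb))
      stop("the two inputs must share their patient columns")
    if (!is.null(colnames(xa)) && !is.null(colnames(xb)) &&
        !identical(colnames(xa), colnames(xb)))
      stop("the two inputs must share their patient columns")
    rng <- range(xa, xb)
    n <- ncol(xa)
    patient_ids <- colnames(xa)
  } else {
    xa <- as.matrix(x)
    rng <- range(xa)
    n <- ncol(xa)
    patient_ids <- colnames(xa)
  }
  if (rng[1] < 0 || rng[2] > 1)
    stop("inputs must be scaled to [0, 1] (see minmax_scale)")
  if (n < batch_size)
    message(sprintf("dae: %d patients < batch_size %d; using a single batch",
                    n, batch_size))

  set.seed(seed)
  params <- if (two) .init_two(nrow(xa), nrow(xb), hidden1, hidden)
            else .init_one(nrow(xa), hidden)

  if (corruption == "fixed") {
    set.seed(.epoch_seed(seed, 0L))
    fixed_a <- corrupt(xa, noise_factor, unit = corruption_unit)$values
    if (two) fixed_b <- corrupt(xb, noise_factor,
                                unit = corruption_unit)$values
  }

  loss_history <- numeric(0)
  for (e in seq_len(epochs)) {
    set.seed(.epoch_seed(seed, e))
    if (corruption == "per_epoch") {
      ca <- corrupt(xa, noise_factor, unit = corruption_unit)$values
      if (two) cb <- corrupt(xb, noise_factor,
                             unit = corruption_unit)$values
    } else {
      ca <- fixed_a
      if (two) cb <- fixed_b
    }
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / batch_size))
    tot <- 0
    for (idx in batches) {
      nb <- length(idx)
      if (two) {
        dm <- if (dropout_rate > 0) .dropout_mask(hidden, nb, dropout_rate)
        fb <- .fb_two(params, ca[, idx, drop = FALSE],
                      cb[, idx, drop = FALSE],
                      xa[, idx, drop = FALSE], xb[, idx, drop = FALSE],
                      dm, dropout_rate)
        params$W1_a <- params$W1_a - learning_rate * fb$gW1_a
        params$W1_b <- params$W1_b - learning_rate * fb$gW1_b
        params$W2 <- params$W2 - learning_rate * fb$gW2
        params$b1_a <- params$b1_a - learning_rate * fb$g_b1_a
        params$b1_b <- params$b1_b - learning_rate * fb$g_b1_b
        params$b2 <- params$b2 - learning_rate * fb$g_b2
        params$b_dec_a <- params$b_dec_a - learning_rate * fb$g_bdec_a
        params$b_dec_b <- params$b_dec_b - learning_rate * fb$g_bdec_b
        params$b_dec_mid <- params$b_dec_mid - learning_rate * fb$g_bdec_mid
      } else {
        dm <- if (dropout_rate > 0) .dropout_mask(hidden, nb, dropout_rate)
        fb <- .fb_one(params, ca[, idx, drop = FALSE],
                      xa[, idx, drop = FALSE], dm, dropout_rate)
        params$W <- params$W - learning_rate * fb$gW
        params$b <- params$b - learning_rate * fb$g_b
        params$b_dec <- params$b_dec - learning_rate * fb$g_bdec
      }
      tot <- tot + fb$loss * nb
    }
    loss_history <- c(loss_history, tot / n)
  }

  ## feature activities on the clean inputs, inference mode
  if (two) {
    act <- t(forward_two(params, xa, xb, train_mode = FALSE)$encode2)
  } else {
    act <- t(forward_one(params, xa, train_mode = FALSE)$encode)
  }
  colnames(act) <- sprintf("F%03d", seq_len(hidden))
  rownames(act) <- patient_ids

  structure(list(
    kind = if (two) "two" else "one",
    params = params,
    loss_history = loss_history,
    activity = act,
    x = if (two) list(a = xa, b = xb) else xa,
    gene_ids = if (two) list(a = rownames(xa), b = rownames(xb))
               else rownames(xa),
    patient_ids = patient_ids,
    config = list(hidden = hidden, hidden1 = if (two) hidden1 else NA,
                  noise_factor = noise_factor,
                  learning_rate = learning_rate, batch_size = batch_size,
                  epochs = epochs, dropout_rate = dropout_rate,
                  seed = seed, corruption = corruption,
                  corruption_unit = corruption_unit)),
    class = "dae")
}

#' @export
print.dae <- function(x, ...) {
  cat(sprintf("Denoising autoencoder (%s-input, tied weights)\n", x$kind))
  if (x$kind == "one") {
    cat(sprintf("  %d genes -> %d features\n",
                nrow(x$params$W), ncol(x$params$W)))
  } else {
    cat(sprintf("  (%d, %d) genes -> %d + %d -> %d features\n",
                nrow(x$params$W1_a), nrow(x$params$W1_b),
                ncol(x$params$W1_a), ncol(x$params$W1_b),
                ncol(x$params$W2)))
  }
  cat(sprintf("  %d patients, %d epochs trained", length(x$patient_ids),
              length(x$loss_history)))
  if (length(x$loss_history) > 0)
    cat(sprintf(", final mean BCE %.4f", utils::tail(x$loss_history, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.dae <- function(object, ...) {
  cat(sprintf("Denoising autoencoder (%s-input)\n", object$kind))
  cfg <- object$config
  cat(sprintf(
    "  noise %.2f, lr %.3g, batch %d, epochs %d, dropout %.2f, seed %d\n",
    cfg$noise_factor, cfg$learning_rate, cfg$batch_size, cfg$epochs,
    cfg$dropout_rate, cfg$seed))
  if (length(object$loss_history) > 0)
    cat(sprintf("  mean BCE: first epoch %.4f, final epoch %.4f\n",
                object$loss_history[1],
                utils::tail(object$loss_history, 1)))
  cat(sprintf("  activity: %d patients x %d features, range [%.3f, %.3f]\n",
              nrow(object$activity), ncol(object$activity),
              min(object$activity), max(object$activity)))
  invisible(object)
}

#' Feature activities or reconstructions from a fitted autoencoder
#'
#' @param object a fitted `dae`.
#' @param newdata optional new input (matrix, or list of two for a
#'   two-input model); defaults to the training input.
#' @param type `"features"` (patients x hidden activity matrix) or
#'   `"reconstruction"`.
#' @param ... unused.
#' @return a matrix, or for `type = "reconstruction"` on a two-input model,
#'   a list of two matrices.
#' @export
predict.dae <- function(object, newdata = NULL,
                        type = c("features", "reconstruction"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "features") return(object$activity)
    newdata <- object$x
  }
  if (object$kind == "one") {
    fw <- forward_one(object$params, newdata, train_mode = FALSE)
    if (type == "features") {
      act <- t(fw$encode)
      colnames(act) <- colnames(object$activity)
      act
    } else fw$reconstruction
  } else {
    fw <- forward_two(object$params, newdata[[1]], newdata[[2]],
                      train_mode = FALSE)
    if (type == "features") {
      act <- t(fw$encode2)
      colnames(act) <- colnames(object$activity)
      act
    } else list(a = fw$recon_a, b = fw$recon_b)
  }
}

#' @export
fitted.dae <- function(object, ...) object$activity

#' Encode-layer weights of a fitted autoencoder
#'
#' For the one-input model, the genes x hidden matrix `W`; for the
#' two-input model, a list with `W1_a`, `W1_b` and `W2`.
#'
#' @param object a fitted `dae`.
#' @param ... unused.
#' @export
coef.dae <- function(object, ...) {
  if (object$kind == "one") object$params$W
  else object$params[c("W1_a", "W1_b", "W2")]
}

#' @export
residuals.dae <- function(object, ...) {
  rec <- predict(object, newdata = object$x, type = "reconstruction")
  if (object$kind == "one") object$x - rec
  else list(a = object$x$a - rec$a, b = object$x$b - rec$b)
}

#' Training-loss curve of a fitted autoencoder
#'
#' @param x a fitted `dae`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dae <- function(x, ...) {
  if (length(x$loss_history) == 0) {
    message("no training epochs to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "mean binary cross-entropy", ...)
  invisible(x)
}

#' Serialize a fitted autoencoder to portable text files
#'
#' Each parameter array is written as a tab-separated matrix and a JSON
#' sidecar records the architecture, training configuration and loss
#' history.
#'
#' @param object a fitted `dae`.
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
save_dae <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(object$params)) {
    p <- object$params[[nm]]
    utils::write.table(as.matrix(p), file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  meta <- list(kind = object$kind, config = object$config,
               loss_history = object$loss_history,
               param_dims = lapply(object$params,
                                   function(p) dim(as.matrix(p))),
               gene_ids = object$gene_ids,
               patient_ids = object$patient_ids)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load an autoencoder serialized by [save_dae()]
#'
#' The stored input matrices are not part of the serialization, so
#' [predict.dae()] on the loaded object requires `newdata`.
#'
#' @param dir directory written by [save_dae()].
#' @return a `dae` object (without the training data).
#' @export
load_dae <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  params <- lapply(stats::setNames(nm = names(meta$param_dims)),
                   function(nm) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                     sep = "\t"))
    dimnames(m) <- NULL
    ## biases (names starting with "b") were vectors saved as one column
    if (startsWith(nm, "b")) as.vector(m) else m
  })
  structure(list(kind = meta$kind, params = params,
                 loss_history = meta$loss_history, activity = NULL,
                 x = NULL, gene_ids = meta$gene_ids,
                 patient_ids = meta$patient_ids,
                 config = meta$config),
            class = "dae")
}
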