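test_that("sigmoid is exact at 0, symmetric, and stable at large inputs", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(-3.7), 1 - sigmoid(3.7))
  for (x in c(-50, 50, -500, 500)) {
    v <- sigmoid(x)
    expect_true(v > 0 && v < 1)
  }
})

test_that("corruption zeroes exactly the configured fraction per patient", {
  set.seed(1)
  x <- matrix(runif(8 * 5), 8, 5)
  out <- corrupt(x, noise_factor = 0.25, seed = 2)
  expect_equal(unname(colSums(out$mask)), rep(2, 5))  # round(0.25 * 8)
  expect_true(all(out$values[out$mask] == 0))
  expect_equal(out$values[!out$mask], x[!out$mask])

  # noise 0 is the identity with an empty mask
  id <- corrupt(x, noise_factor = 0, seed = 2)
  expect_identical(id$values, x)
  expect_false(any(id$mask))

  # exact total masked fraction on a large matrix
  big <- matrix(runif(1000 * 50), 1000, 50)
  mb <- corrupt(big, 0.25, seed = 3)
  expect_equal(mean(mb$mask), 0.25)

  # gene-row mode zeroes whole rows
  gr <- corrupt(x, 0.25, seed = 4, unit = "gene")
  expect_equal(sum(rowSums(gr$mask) == 5), 2)
  expect_error(corrupt(x, 1.2), "invalid config")
})

test_that("binary cross-entropy matches a brute-force elementwise sum", {
  expect_equal(bce_loss(0.5, 0.5), log(2))
  suppressMessages(expect_lt(bce_loss(c(0, 1), c(0, 1)), 1e-10))

  set.seed(5)
  t_ <- runif(10)
  o <- runif(10, 0.05, 0.95)
  brute <- -sum(t_ * log(o) + (1 - t_) * log(1 - o)) / 10
  expect_equal(bce_loss(t_, o), brute)
})

test_that("one-input forward matches hand-computed matrix arithmetic", {
  # zero parameters: everything is sigmoid(0) = 0.5
  p0 <- list(W = matrix(0, 3, 2), b = c(0, 0), b_dec = c(0, 0, 0))
  f0 <- forward_one(p0, c(0.2, 0.8, 0.5))
  expect_equal(unname(f0$encode[, 1]), c(0.5, 0.5))
  expect_equal(unname(f0$reconstruction[, 1]), c(0.5, 0.5, 0.5))

  W <- matrix(c(0.5, -0.2, 0.1, 0.3, 0.7, -0.4), 3, 2)
  p <- list(W = W, b = c(0.1, -0.1), b_dec = c(0.05, 0, -0.05))
  x <- c(0.9, 0.1, 0.6)
  enc <- 1 / (1 + exp(-(t(W) %*% x + p$b)))
  rec <- 1 / (1 + exp(-(W %*% enc + p$b_dec)))
  f <- forward_one(p, x)
  expect_equal(f$encode, enc, tolerance = 1e-12)
  expect_equal(f$reconstruction, rec, tolerance = 1e-12)

  # inference mode is deterministic
  expect_identical(forward_one(p, x), forward_one(p, x))
  expect_error(forward_one(p, c(1, 2)), "dimension mismatch")
})

test_that("two-input forward matches the hand-computed chain and is symmetric", {
  p0 <- list(W1_a = matrix(0, 4, 2), W1_b = matrix(0, 4, 2),
             b1_a = numeric(2), b1_b = numeric(2),
             W2 = matrix(0, 4, 2), b2 = numeric(2),
             b_dec_a = numeric(4), b_dec_b = numeric(4),
             b_dec_mid = numeric(4))
  f0 <- forward_two(p0, runif(4), runif(4))
  expect_equal(unname(f0$encode2[, 1]), c(0.5, 0.5))
  expect_equal(unname(f0$recon_a[, 1]), rep(0.5, 4))

  set.seed(6)
  p <- list(W1_a = matrix(rnorm(8, sd = 0.5), 4, 2),
            W1_b = matrix(rnorm(8, sd = 0.5), 4, 2),
            b1_a = rnorm(2, sd = 0.1), b1_b = rnorm(2, sd = 0.1),
            W2 = matrix(rnorm(8, sd = 0.5), 4, 2), b2 = rnorm(2, sd = 0.1),
            b_dec_a = rnorm(4, sd = 0.1), b_dec_b = rnorm(4, sd = 0.1),
            b_dec_mid = rnorm(4, sd = 0.1))
  xa <- runif(4); xb <- runif(4)
  sg <- function(z) 1 / (1 + exp(-z))
  ha <- sg(t(p$W1_a) %*% xa + p$b1_a)
  hb <- sg(t(p$W1_b) %*% xb + p$b1_b)
  cc <- rbind(ha, hb)
  h2 <- sg(t(p$W2) %*% cc + p$b2)
  mid <- sg(p$W2 %*% h2 + p$b_dec_mid)
  ra <- sg(p$W1_a %*% mid[1:2, , drop = FALSE] + p$b_dec_a)
  rb <- sg(p$W1_b %*% mid[3:4, , drop = FALSE] + p$b_dec_b)
  f <- forward_two(p, xa, xb)
  expect_equal(f$encode2, h2, tolerance = 1e-12)
  expect_equal(f$recon_a, ra, tolerance = 1e-12)
  expect_equal(f$recon_b, rb, tolerance = 1e-12)

  # swapping the sources along with their parameters swaps reconstructions
  pswap <- list(W1_a = p$W1_b, W1_b = p$W1_a, b1_a = p$b1_b,
                b1_b = p$b1_a,
                W2 = rbind(p$W2[3:4, ], p$W2[1:2, ]), b2 = p$b2,
                b_dec_a = p$b_dec_b, b_dec_b = p$b_dec_a,
                b_dec_mid = c(p$b_dec_mid[3:4], p$b_dec_mid[1:2]))
  fs <- forward_two(pswap, xb, xa)
  expect_equal(fs$recon_a, f$recon_b, tolerance = 1e-12)
  expect_equal(fs$recon_b, f$recon_a, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  d <- 5; h <- 3; n <- 4
  params <- list(W = matrix(rnorm(d * h, sd = 0.4), d, h),
                 b = rnorm(h, sd = 0.1), b_dec = rnorm(d, sd = 0.1))
  xc <- matrix(runif(d * n), d, n)
  tgt <- matrix(runif(d * n), d, n)
  mask <- matrix(rbinom(h * n, 1, 0.5), h, n)  # fixed dropout pattern

  fb <- daesurv:::.fb_one(params, xc, tgt, mask, 0.5)
  eps <- 1e-6
  loss_at <- function(p) daesurv:::.fb_one(p, xc, tgt, mask, 0.5)$loss
  rel_err <- function(a, num) max(abs(a - num) / pmax(abs(num), 1e-8))

  num_gW <- params$W
  for (i in seq_len(d)) for (j in seq_len(h)) {
    pp <- params; pm <- params
    pp$W[i, j] <- pp$W[i, j] + eps
    pm$W[i, j] <- pm$W[i, j] - eps
    num_gW[i, j] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
  }
  expect_lt(rel_err(fb$gW, num_gW), 1e-5)

  num_gb <- vapply(seq_len(h), function(j) {
    pp <- params; pm <- params
    pp$b[j] <- pp$b[j] + eps; pm$b[j] <- pm$b[j] - eps
    (loss_at(pp) - loss_at(pm)) / (2 * eps)
  }, numeric(1))
  expect_lt(rel_err(fb$g_b, num_gb), 1e-5)

  num_gbd <- vapply(seq_len(d), function(i) {
    pp <- params; pm <- params
    pp$b_dec[i] <- pp$b_dec[i] + eps; pm$b_dec[i] <- pm$b_dec[i] - eps
    (loss_at(pp) - loss_at(pm)) / (2 * eps)
  }, numeric(1))
  expect_lt(rel_err(fb$g_bdec, num_gbd), 1e-5)
})

test_that("two-input gradients match finite differences", {
  set.seed(8)
  da <- 4; db <- 4; h1 <- 2; h <- 2; n <- 3
  params <- list(W1_a = matrix(rnorm(da * h1, sd = 0.4), da, h1),
                 W1_b = matrix(rnorm(db * h1, sd = 0.4), db, h1),
                 b1_a = rnorm(h1, 0.1), b1_b = rnorm(h1, 0.1),
                 W2 = matrix(rnorm(2 * h1 * h, sd = 0.4), 2 * h1, h),
                 b2 = rnorm(h, 0.1),
                 b_dec_a = rnorm(da, 0.1), b_dec_b = rnorm(db, 0.1),
                 b_dec_mid = rnorm(2 * h1, 0.1))
  xa <- matrix(runif(da * n), da, n); xb <- matrix(runif(db * n), db, n)
  ta <- matrix(runif(da * n), da, n); tb <- matrix(runif(db * n), db, n)
  mask <- matrix(rbinom(h * n, 1, 0.5), h, n)
  fb <- daesurv:::.fb_two(params, xa, xb, ta, tb, mask, 0.5)
  loss_at <- function(p)
    daesurv:::.fb_two(p, xa, xb, ta, tb, mask, 0.5)$loss
  eps <- 1e-6
  gmap <- c(W1_a = "gW1_a", W2 = "gW2", b1_b = "g_b1_b", b2 = "g_b2",
            b_dec_mid = "g_bdec_mid")
  for (nm in names(gmap)) {
    analytic <- fb[[gmap[[nm]]]]
    expect_false(is.null(analytic))
    num <- array(0, dim = if (is.matrix(params[[nm]]))
      dim(params[[nm]]) else length(params[[nm]]))
    for (k in seq_along(params[[nm]])) {
      pp <- params; pm <- params
      pp[[nm]][k] <- pp[[nm]][k] + eps
      pm[[nm]][k] <- pm[[nm]][k] - eps
      num[k] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    }
    expect_lt(max(abs(analytic - num) / pmax(abs(num), 1e-8)), 1e-5)
  }
})

test_that("dropout zeroes about half the feature layer and rescales survivors", {
  set.seed(9)
  m <- daesurv:::.dropout_mask(500, 400, 0.5)
  expect_lt(abs(mean(!m) - 0.5), 0.01)
})

test_that("training descends, is reproducible, and ties the decode weights", {
  set.seed(10)
  b <- simulate_bundle(sim_config(n_patients = 70, n_genes = 200,
                                  seed = 12))
  pp <- suppressMessages(preprocess_bundle(b))

  f1 <- suppressMessages(dae(pp$expr, hidden = 8, epochs = 15, seed = 2))
  f2 <- suppressMessages(dae(pp$expr, hidden = 8, epochs = 15, seed = 2))
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$activity, f2$activity)
  expect_lt(tail(f1$loss_history, 1), f1$loss_history[1])

  # feature activities live strictly inside (0, 1)
  expect_true(all(f1$activity > 0 & f1$activity < 1))
  expect_equal(ncol(f1$activity), 8)
  expect_identical(colnames(f1$activity)[1], "F001")

  # tied weights: parameter count is input_dim*hidden + hidden + input_dim,
  # while an untied autoencoder would carry a second weight matrix
  n_par <- length(f1$params$W) + length(f1$params$b) +
    length(f1$params$b_dec)
  d <- nrow(pp$expr)
  expect_equal(n_par, d * 8 + 8 + d)
  untied <- 2 * d * 8 + 8 + d
  expect_lt(n_par, untied)

  # epochs = 0 returns the initialized model with an empty loss history
  f0 <- suppressMessages(dae(pp$expr, hidden = 8, epochs = 0, seed = 2))
  expect_length(f0$loss_history, 0)
  expect_equal(dim(f0$activity), c(ncol(pp$expr), 8))
})

test_that("the noiseless dropout-free configuration reconstructs at least as well", {
  b <- simulate_bundle(sim_config(n_patients = 40, n_genes = 120,
                                  seed = 13))
  pp <- suppressMessages(preprocess_bundle(b))
  plain <- suppressMessages(dae(pp$expr, hidden = 8, epochs = 800,
                                noise_factor = 0, dropout_rate = 0,
                                seed = 3))
  noisy <- suppressMessages(dae(pp$expr, hidden = 8, epochs = 800,
                                seed = 3))
  # evaluate both as clean-input reconstructions (inference mode)
  loss_of <- function(f) bce_loss(pp$expr,
                                  predict(f, pp$expr,
                                          type = "reconstruction"))
  expect_lte(loss_of(plain), loss_of(noisy))
})

test_that("two-input training runs, descends and yields in-range activities", {
  b <- simulate_bundle(sim_config(n_patients = 60, n_genes = 150,
                                  seed = 14))
  pp <- suppressMessages(preprocess_bundle(b))
  f <- suppressMessages(dae(list(pp$expr, pp$cna), hidden = 6,
                            hidden1 = 10, epochs = 15, seed = 4))
  expect_lt(tail(f$loss_history, 1), f$loss_history[1])
  expect_true(all(f$activity > 0 & f$activity < 1))
  expect_equal(ncol(f$activity), 6)
  expect_equal(ncol(f$params$W1_a), 10)
  expect_equal(dim(f$params$W2), c(20, 6))
})

test_that("fitted models serialize to text and load back identically", {
  b <- simulate_bundle(sim_config(n_patients = 40, n_genes = 100,
                                  seed = 15))
  pp <- suppressMessages(preprocess_bundle(b))
  f <- suppressMessages(dae(pp$expr, hidden = 5, epochs = 3, seed = 5))
  dir <- withr::local_tempdir()
  save_dae(f, dir)
  g <- load_dae(dir)
  expect_equal(g$params$W, unname(f$params$W), tolerance = 1e-10)
  expect_equal(g$params$b, f$params$b, tolerance = 1e-10)
  expect_equal(g$loss_history, f$loss_history, tolerance = 1e-10)
  # predictions from the reloaded parameters agree
  expect_equal(unname(predict(g, pp$expr)),
               unname(predict(f, pp$expr)), tolerance = 1e-8)
})
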