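# Independent oracles used across the suite. Each is a deliberately naive
# computation (enumeration, brute-force loop, grid search) kept separate
# from the package's implementation path.

# Two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
# with the probability-ordering rule.
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breslow partial log-likelihood evaluated directly from its definition.
breslow_loglik <- function(b, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- which(times >= times[i])
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

# Maximize the Breslow partial likelihood on a grid (oracle for the
# Newton-Raphson fit).
grid_cox_b <- function(x, times, events, lo = -5, hi = 5, tol = 1e-4) {
  grid <- seq(lo, hi, by = tol)
  ll <- vapply(grid, breslow_loglik, numeric(1), x = x, times = times,
               events = events)
  grid[which.max(ll)]
}

# Naive O(n^3) complete-linkage agglomeration: returns sorted merge
# heights.
naive_complete_heights <- function(X) {
  d <- as.matrix(dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Adjusted Rand index between two label vectors (contingency-table form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Small deterministic survival fixture with a binary covariate.
toy_surv <- function() {
  list(times = c(2, 4, 5, 7, 9, 11, 12, 15),
       events = c(1, 1, 0, 1, 1, 0, 1, 1),
       x = c(1, 1, 0, 1, 0, 1, 0, 0))
}
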