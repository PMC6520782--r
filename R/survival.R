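#' Kaplan-Meier curves and log-rank comparison of patient groups
#'
#' Product-limit survival estimate per group (via [survival::survfit()])
#' and the log-rank test across groups (via [survival::survdiff()]). When
#' no events occur anywhere the log-rank statistic is undefined; the
#' p-value is reported as 1 with a warning.
#'
#' @param times non-negative survival times.
#' @param events event indicators in \{0, 1\} (1 = death observed).
#' @param groups per-patient group labels, at least two non-empty groups.
#' @return list with `fit` (the `survfit` object), `chisq` (log-rank
#'   statistic), `df` and `p_value`.
#' @export
km_estimate <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two non-empty groups")
  s <- survival::Surv(times, events)
  fit <- survival::survfit(s ~ groups)
  if (sum(events) == 0) {
    warning("no events observed; log-rank test undefined, reporting p = 1")
    return(list(fit = fit, chisq = NA_real_, df = NA_integer_,
                p_value = 1))
  }
  sd <- survival::survdiff(s ~ groups)
  df <- length(sd$n) - 1
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

## Breslow partial log-likelihood, score and information for a single
## covariate. Risk sets computed by sorting on time (descending) so the
## cumulative sums at each event index cover all subjects with t_j >= t_i,
## ties included.
.cox_breslow <- function(b, x, times, events, prep = NULL) {
  if (is.null(prep)) prep <- .cox_prep(x, times, events)
  eta <- b * prep$x
  w <- exp(eta)
  s0 <- cumsum(w)
  s1 <- cumsum(w * prep$x)
  s2 <- cumsum(w * prep$x^2)
  r0 <- s0[prep$risk_idx]
  r1 <- s1[prep$risk_idx]
  r2 <- s2[prep$risk_idx]
  list(loglik = sum(eta[prep$ev] - log(r0)),
       score = sum(prep$x[prep$ev] - r1 / r0),
       info = sum(r2 / r0 - (r1 / r0)^2))
}

## Sort subjects by time (descending) and, for each event, find the index
## of the last subject sharing its time, so cumulative sums at that index
## cover the full risk set {j : t_j >= t_i}, ties included.
.cox_prep <- function(x, times, events) {
  ord <- order(times, decreasing = TRUE)
  x <- x[ord]
  times <- times[ord]
  events <- events[ord]
  n <- length(times)
  last_tie <- integer(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && times[j + 1] == times[i]) j <- j + 1L
    last_tie[i] <- j
  }
  ev <- which(events == 1)
  list(x = x, ev = ev, risk_idx = last_tie[ev])
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits `h(t) = h0(t) * exp(b x)` for a single covariate by maximizing the
#' Breslow partial likelihood with Newton-Raphson (convergence when the
#' step falls below 1e-8, at most 50 iterations). Reports the hazard ratio
#' `exp(b)` with a Wald 95% confidence interval and p-value. A monotone
#' likelihood (perfect separation) is flagged and the coefficient capped.
#'
#' @param x per-patient covariate values (e.g. one feature's activities).
#' @param times non-negative survival times.
#' @param events event indicators in \{0, 1\}; at least one event required.
#' @return object of class `cox_result`: list with `b`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `iterations`, `converged`,
#'   `monotone`.
#' @export
cox_univariate <- function(x, times, events) {
  stopifnot(length(x) == length(times), length(x) == length(events))
  if (any(!is.finite(x))) stop("covariate must be finite")
  if (sum(events) == 0) stop("no events observed; Cox fit undefined")
  cap <- 15
  if (stats::sd(x) == 0) {
    res <- list(b = 0, se = Inf, hr = 1, ci_low = 0, ci_high = Inf,
                p_value = 1, iterations = 0L, converged = TRUE,
                monotone = FALSE)
    class(res) <- "cox_result"
    return(res)
  }
  prep <- .cox_prep(x, times, events)
  b <- 0
  converged <- FALSE
  monotone <- FALSE
  it <- 0L
  for (it in seq_len(50L)) {
    d <- .cox_breslow(b, x, times, events, prep)
    if (d$info <= 1e-12) break
    step <- d$score / d$info
    ## dampen wild steps far from the optimum
    if (abs(step) > 5) step <- sign(step) * 5
    b <- b + step
    if (abs(b) > cap) {
      b <- sign(b) * cap
      monotone <- TRUE
      warning("monotone partial likelihood (separation); coefficient capped")
      break
    }
    if (abs(step) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  d <- .cox_breslow(b, x, times, events, prep)
  se <- if (d$info > 0) 1 / sqrt(d$info) else Inf
  z <- b / se
  res <- list(b = b, se = se, hr = exp(b),
              ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
              p_value = 2 * stats::pnorm(-abs(z)),
              iterations = it, converged = converged, monotone = monotone)
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH: b = %.4f (se %.4f), HR = %.4f [%.4f, %.4f], p = %.3g\n",
              x$b, x$se, x$hr, x$ci_low, x$ci_high, x$p_value))
  if (x$monotone) cat("  (monotone likelihood; coefficient capped)\n")
  invisible(x)
}

#' Per-feature univariate Cox table
#'
#' One univariate Cox fit per feature column of the activity matrix,
#' assembled into a table of coefficients, hazard ratios, 95% CIs and
#' Wald p-values. These coefficients are the weights of the risk score.
#'
#' @param features patients x features activity matrix.
#' @param times,events survival outcome aligned with the rows.
#' @param joint fit all features in one ridge-stabilized Cox model instead
#'   of separate univariate fits (`theta` is the ridge penalty). The
#'   univariate fits are the default.
#' @param theta ridge penalty for the joint fit.
#' @return data frame with columns `feature_id`, `b`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
cox_feature_table <- function(features, times, events, joint = FALSE,
                              theta = 1) {
  features <- as.matrix(features)
  ids <- colnames(features)
  if (is.null(ids)) ids <- sprintf("F%03d", seq_len(ncol(features)))
  if (joint) {
    fit <- survival::coxph(survival::Surv(times, events) ~
                             survival::ridge(features, theta = theta,
                                             scale = FALSE))
    b <- unname(stats::coef(fit))
    se <- sqrt(diag(stats::vcov(fit)))
    z <- b / se
    out <- data.frame(feature_id = ids, b = b, hr = exp(b),
                      ci_low = exp(b - 1.96 * se),
                      ci_high = exp(b + 1.96 * se),
                      p_value = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(seq_len(ncol(features)), function(i) {
    r <- suppressWarnings(cox_univariate(features[, i], times, events))
    data.frame(feature_id = ids[i], b = r$b, hr = r$hr, ci_low = r$ci_low,
               ci_high = r$ci_high, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cox-coefficient-weighted risk scores
#'
#' The per-patient linear combination `r_p = sum_i b_i * a_pi` of feature
#' activities weighted by their univariate Cox coefficients.
#'
#' @param features patients x features activity matrix.
#' @param coefficients one Cox coefficient per feature column (a numeric
#'   vector or a [cox_feature_table()] data frame).
#' @return named numeric vector of per-patient scores.
#' @export
risk_score <- function(features, coefficients) {
  features <- as.matrix(features)
  if (is.data.frame(coefficients)) {
    if (!is.null(colnames(features)) &&
        !is.null(coefficients$feature_id)) {
      idx <- match(colnames(features), coefficients$feature_id)
      if (any(is.na(idx))) stop("coefficients missing for some features")
      coefficients <- coefficients$b[idx]
    } else coefficients <- coefficients$b
  }
  if (length(coefficients) != ncol(features))
    stop("dimension mismatch: need one coefficient per feature column")
  drop(features %*% coefficients)
}

#' Binarize risk scores at a quantile cutoff
#'
#' The cutoff is the empirical quantile of the scores at `prob`
#' (linear-interpolation definition, [stats::quantile()] type 7). Patients
#' with a score strictly above the cutoff are high-risk; ties at the cutoff
#' go to the low-risk group.
#'
#' @param scores per-patient risk scores, at least two distinct values.
#' @param prob quantile used as the cutoff (default 0.55, i.e. the lowest
#'   55% of scores form the low-risk group).
#' @param coefficients optional per-feature coefficients, carried along for
#'   provenance.
#' @return object of class `risk_profile`: list with `scores`, `cutoff`,
#'   `group` (factor, "high"/"low"), `prob`, `coefficients`.
#' @export
binarize_risk <- function(scores, prob = 0.55, coefficients = NULL) {
  if (length(unique(scores)) < 2)
    stop("all scores identical; no cutoff exists")
  if (prob <= 0 || prob >= 1) stop("invalid config: prob must be in (0, 1)")
  cutoff <- stats::quantile(scores, prob, names = FALSE, type = 7)
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  names(group) <- names(scores)
  structure(list(scores = scores, cutoff = cutoff, group = group,
                 prob = prob, coefficients = coefficients),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("Risk profile: cutoff %.4f (quantile %.2f)\n", x$cutoff,
              x$prob))
  print(table(x$group))
  invisible(x)
}

#' Survival evaluation of a risk profile
#'
#' Compares the high- and low-risk groups by Kaplan-Meier curves and the
#' log-rank test, and fits a univariate Cox model to the continuous score,
#' yielding a hazard-ratio report (HR, 95% CI bounds, Wald p).
#'
#' @param profile a `risk_profile`.
#' @param times,events survival outcome aligned with the scores.
#' @return list with `km` (from [km_estimate()]), `cox` (the continuous
#'   score's `cox_result`), and `report` (one-row data frame: HR, CI
#'   bounds, Cox p, log-rank p).
#' @export
evaluate_risk_groups <- function(profile, times, events) {
  km <- km_estimate(times, events, profile$group)
  cox <- suppressWarnings(cox_univariate(profile$scores, times, events))
  report <- data.frame(hr = cox$hr, ci_low = cox$ci_low,
                       ci_high = cox$ci_high, cox_p = cox$p_value,
                       logrank_p = km$p_value)
  list(km = km, cox = cox, report = report)
}
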