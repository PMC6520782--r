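test_that("KM product-limit estimates match hand computation", {
  # n = 4, deaths at t = 1 and t = 2, no censoring elsewhere
  times <- c(1, 2, 3, 3)
  events <- c(1, 1, 0, 0)
  groups <- rep("all", 4)
  # single group is invalid for the comparison wrapper; compute directly
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  expect_equal(summary(fit, times = c(1, 2))$surv, c(3 / 4, 1 / 2))

  # two groups with identical outcomes: log-rank statistic 0, p = 1
  km <- km_estimate(c(times, times), c(events, events),
                    rep(c("a", "b"), each = 4))
  expect_equal(km$chisq, 0, tolerance = 1e-10)
  expect_equal(km$p_value, 1, tolerance = 1e-10)

  # no events anywhere: p reported as 1 with a warning
  expect_warning(km0 <- km_estimate(c(5, 6, 7, 8), rep(0, 4),
                                    c("a", "a", "b", "b")),
                 "no events")
  expect_equal(km0$p_value, 1)

  expect_error(km_estimate(c(1, 2), c(1, 1), c("a", "a")), "two")
  expect_error(km_estimate(c(-1, 2), c(1, 1), c("a", "b")),
               "non-negative")
})

test_that("Newton-Raphson Cox fit matches the grid-search partial-likelihood oracle", {
  fx <- toy_surv()
  fit <- cox_univariate(fx$x, fx$times, fx$events)
  b_grid <- grid_cox_b(fx$x, fx$times, fx$events)
  expect_lt(abs(fit$b - b_grid), 1e-3)
  expect_equal(fit$hr, exp(fit$b))
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # additional <=10-patient fixtures, including ties
  fixtures <- list(
    list(times = c(1, 1, 2, 3, 4, 5), events = c(1, 1, 0, 1, 1, 0),
         x = c(0.2, 1.5, -0.3, 0.8, -1.1, 0.5)),
    list(times = c(3, 3, 3, 6, 7, 8, 9, 10, 11, 12),
         events = c(1, 0, 1, 1, 0, 1, 1, 0, 1, 0),
         x = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)),
    list(times = c(2, 4, 4, 6, 8), events = c(1, 1, 1, 1, 1),
         x = c(-0.5, 0.1, 0.7, -0.2, 1.3)))
  for (f in fixtures) {
    fit <- cox_univariate(f$x, f$times, f$events)
    expect_lt(abs(fit$b - grid_cox_b(f$x, f$times, f$events)), 1e-3)
  }

  # cross-check against the survival package on the toy fixture
  cph <- survival::coxph(survival::Surv(fx$times, fx$events) ~ fx$x,
                         ties = "breslow")
  expect_equal(cox_univariate(fx$x, fx$times, fx$events)$b,
               unname(coef(cph)), tolerance = 1e-6)
})

test_that("degenerate Cox inputs are handled as specified", {
  expect_error(cox_univariate(c(1, 2), c(3, 4), c(0, 0)), "no events")
  cst <- cox_univariate(rep(2, 6), c(1, 2, 3, 4, 5, 6),
                        c(1, 0, 1, 1, 0, 1))
  expect_equal(cst$b, 0)
  expect_equal(cst$hr, 1)
  # perfect separation: covariate orders exactly with hazard
  xs <- c(10, 9, 8, -8, -9, -10)
  expect_warning(sep <- cox_univariate(xs, c(1, 2, 3, 100, 101, 102),
                                       rep(1, 6)), "monotone")
  expect_true(sep$monotone)
  expect_lte(abs(sep$b), 15)
})

test_that("Cox recovers a generative log-HR of 0.8 with small bias", {
  est <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    x <- rnorm(n)
    t_ev <- rexp(n, rate = 0.001 * exp(0.8 * x))
    cens <- runif(n, 0, quantile(t_ev, 0.9) * 2)
    cox_univariate(x, pmin(t_ev, cens), as.integer(t_ev <= cens))$b
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.1)
})

test_that("the joint ridge fit returns one stabilized coefficient per feature", {
  set.seed(22)
  act <- matrix(runif(80 * 4), 80, 4,
                dimnames = list(sprintf("P%02d", 1:80), paste0("F", 1:4)))
  tt <- rexp(80, 0.01 * exp(0.6 * act[, 1]))
  ev <- rbinom(80, 1, 0.8)
  jt <- cox_feature_table(act, tt, ev, joint = TRUE)
  expect_equal(jt$feature_id, paste0("F", 1:4))
  expect_true(all(is.finite(jt$b)))
  expect_equal(jt$hr, exp(jt$b))
})

test_that("risk scores are the coefficient-weighted activity sums", {
  expect_equal(unname(risk_score(matrix(c(0.5, 0.5), 1, 2), c(1, 2))), 1.5)
  set.seed(20)
  act <- matrix(runif(15), 5, 3,
                dimnames = list(paste0("p", 1:5), paste0("F", 1:3)))
  b <- rnorm(3)
  brute <- vapply(1:5, function(p) sum(b * act[p, ]), numeric(1))
  expect_equal(unname(risk_score(act, b)), brute)
  expect_equal(unname(risk_score(act, c(0, 0, 0))), rep(0, 5))
  # linearity in the activities
  expect_equal(risk_score(act * 3, b), 3 * risk_score(act, b))
  expect_error(risk_score(act, c(1, 2)), "dimension mismatch")
})

test_that("quantile binarization yields the configured low-risk fraction", {
  pr <- binarize_risk(1:100, prob = 0.55)
  expect_equal(sum(pr$group == "low"), 55)
  expect_equal(sum(pr$group == "high"), 45)

  # median split on symmetric scores
  pr2 <- binarize_risk(c(-3, -2, -1, 1, 2, 3), prob = 0.5)
  expect_equal(sum(pr2$group == "low"), 3)

  # shift invariance of the grouping
  set.seed(21)
  sc <- rnorm(200)
  g1 <- binarize_risk(sc)$group
  g2 <- binarize_risk(sc + 100)$group
  expect_identical(g1, g2)

  # low-risk fraction within 1/n of prob for distinct scores
  frac <- mean(binarize_risk(sc, 0.55)$group == "low")
  expect_lt(abs(frac - 0.55), 1 / 200 + 1e-9)

  expect_error(binarize_risk(rep(1, 5)), "identical")
})

test_that("risk-group evaluation is deterministic and reports the Table-3 shape", {
  fx <- toy_surv()
  pr <- binarize_risk(c(0.9, 0.8, 0.2, 0.7, 0.1, 0.6, 0.3, 0.4))
  e1 <- evaluate_risk_groups(pr, fx$times, fx$events)
  e2 <- evaluate_risk_groups(pr, fx$times, fx$events)
  expect_identical(e1$report, e2$report)
  expect_named(e1$report, c("hr", "ci_low", "ci_high", "cox_p",
                            "logrank_p"))
})

test_that("null risk scores give uniform log-rank p-values", {
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 100
    t_ev <- rexp(n, 0.01)
    cens <- runif(n, 0, 300)
    pr <- binarize_risk(rnorm(n))
    km_estimate(pmin(t_ev, cens), as.integer(t_ev <= cens),
                pr$group)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("risk scores built from the planted hazard covariate recover the effect", {
  hits <- 0
  for (s in 1:50) {
    b <- simulate_bundle(sim_config(n_patients = 250, n_genes = 30,
                                    n_latent = 2, hazard_coef = 0.8,
                                    seed = 300 + s))
    fit <- cox_univariate(b$truth$latent_factors[, 1],
                          b$clinical$os_time, b$clinical$os_event)
    hits <- hits + (log(fit$ci_low) <= 0.8 && 0.8 <= log(fit$ci_high))
  }
  expect_gte(hits / 50, 0.9)
})

test_that("high-risk groups from a hazard-linked score have worse survival", {
  ok <- 0
  for (s in 1:20) {
    b <- simulate_bundle(sim_config(n_patients = 300, n_genes = 30,
                                    n_latent = 2, hazard_coef = 0.8,
                                    group_effect = 2, seed = 400 + s))
    pr <- binarize_risk(b$truth$latent_factors[, 1])
    ev <- evaluate_risk_groups(pr, b$clinical$os_time,
                               b$clinical$os_event)
    sf <- summary(ev$km$fit, times = stats::median(b$clinical$os_time),
                  extend = TRUE)
    s_by <- stats::setNames(sf$surv, sf$strata)
    below <- s_by[grep("high", names(s_by))] <
      s_by[grep("low", names(s_by))]
    ok <- ok + (ev$report$logrank_p < 0.01 && below)
  }
  expect_gte(ok / 20, 0.9)
})
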