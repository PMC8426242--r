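test_that("log2p1 maps 0/1/7 to 0/1/3 and rejects negatives", {
  expect_equal(log2p1(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log2p1(-0.1), "non-negative")
})

test_that("cox_fit agrees with the grid-search partial-likelihood oracle on tiny data", {
  for (s in 1:8) {
    set.seed(500 + s)
    n <- 4
    x <- stats::rnorm(n)
    time <- sort(stats::rexp(n, 0.1))      # continuous, no ties
    rec <- surv_records(time, rep(1, n), x = x)
    b_oracle <- oracle_cox_beta(rec$time_months, rec$event, x)
    if (abs(b_oracle) > 15) next   # monotone likelihood: MLE unbounded
    fit <- cox_fit(rec, "x")
    expect_lt(abs(fit$coefficients[["x"]] - b_oracle), 1e-4)
    expect_equal(fit$hr, exp(fit$coefficients[["x"]]))
    expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
  }
})

test_that("cox_fit on a permuted covariate is null and errors are informative", {
  set.seed(6)
  n <- 400
  rec <- surv_records(stats::rexp(n, 0.05), stats::rbinom(n, 1, 0.8),
                      x = stats::rnorm(n))
  fit <- cox_fit(rec, "x")
  expect_lt(abs(fit$coefficients[["x"]]), 3 * fit$se[["x"]])
  rec$const <- 1
  expect_error(cox_fit(rec, "const"), "constant")
  expect_error(cox_fit(rec[rec$event == 0, ], "x"), "event")
  # perfect separation: the covariate orders all event times
  sep <- surv_records(c(1, 2, 3, 4, 10, 11, 12, 13), rep(1, 8),
                      z = c(rep(1, 4), rep(0, 4)))
  expect_error(cox_fit(sep, "z"), "separation|monotone")
})

test_that("stepwise selection keeps a strong effect, rejects pure noise, and records its trace", {
  coh <- generate_cohort(cohort_config(n_patients = 600,
                                       beta = c("bone" = 0.5), seed = 41))
  rec <- coh$records
  set.seed(7)
  rec$noise1 <- stats::rnorm(600)
  rec$noise2 <- stats::rnorm(600)
  sw <- stepwise_cox(rec, c("log2_mtv_bone", "noise1", "noise2"))
  expect_true("log2_mtv_bone" %in% sw$selected)
  expect_equal(sw$trace$action[1], "enter")
  expect_equal(sw$trace$covariate[1], "log2_mtv_bone")
  # two pure-noise candidates: empty model in about (0.95)^2 of seeds
  empty <- vapply(1:30, function(s) {
    set.seed(600 + s)
    rec2 <- surv_records(stats::rexp(120, 0.05), stats::rbinom(120, 1, 0.8),
                         a = stats::rnorm(120), b = stats::rnorm(120))
    sw2 <- stepwise_cox(rec2, c("a", "b"))
    length(sw2$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.75)
  # a rejected entry still leaves a trace row
  set.seed(601)
  rec3 <- surv_records(stats::rexp(80, 0.05), rep(1, 80),
                       a = stats::rnorm(80), b = stats::rnorm(80))
  sw3 <- stepwise_cox(rec3, c("a", "b"))
  if (length(sw3$selected) == 0)
    expect_true("entry rejected" %in% sw3$trace$action)
})

test_that("Gonen-Heller concordance: null is 0.5, matches the pairwise oracle, grows with |beta|", {
  expect_equal(as.numeric(gonen_heller_cpe(rep(0.7, 10))), 0.5)
  expect_true(attr(gonen_heller_cpe(rep(0.7, 10)), "degenerate"))
  for (s in 1:10) {
    set.seed(700 + s)
    eta <- stats::rnorm(sample(5:20, 1))
    expect_equal(as.numeric(gonen_heller_cpe(eta)), oracle_cpe(eta),
                 tolerance = 1e-12)
  }
  # two balanced groups: concordance is monotone in |beta| toward 3/4 + eps
  x <- rep(c(0, 1), each = 10)
  ks <- vapply(c(0.5, 1, 2, 4, 8), function(b)
    as.numeric(gonen_heller_cpe(b * x)), numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_lt(ks[length(ks)], 10 * 10 / (20 * 19 / 2) + 0.5)  # group-balance bound
})

test_that("comparing a model with itself yields delta 0 and p = 1", {
  coh <- generate_cohort(cohort_config(n_patients = 60, seed = 43))
  cmp <- compare_cpe_bootstrap(coh$records, "log2_mtv_whole_body",
                               "log2_mtv_whole_body", B = 50, seed = 1)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p, 1)
})

test_that("a true-signal model beats pure noise in the concordance comparison", {
  coh <- generate_cohort(cohort_config(n_patients = 500,
                                       beta = c("whole_body" = 0.5), seed = 44))
  rec <- coh$records
  set.seed(8)
  rec$noise <- stats::rnorm(500)
  cmp <- compare_cpe_bootstrap(rec, "log2_mtv_whole_body", "noise",
                               B = 200, seed = 2)
  expect_gt(cmp$cpe_a, cmp$cpe_b)
  expect_lt(cmp$p, 0.05)
})

test_that("Kaplan-Meier hand check: four uncensored events step 0.75/0.5/0.25/0, median 2", {
  rec <- surv_records(c(1, 2, 3, 4), rep(1, 4))
  km <- km_estimate(rec)
  cv <- km$curves[[1]]
  expect_equal(cv$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(cv$median, 2)
  # without censoring KM equals the empirical survival function
  set.seed(9)
  t2 <- stats::rexp(40, 0.1)
  km2 <- km_estimate(surv_records(t2, rep(1, 40)))$curves[[1]]
  emp <- vapply(km2$time, function(u) mean(t2 > u), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  # median undefined when the curve never reaches 0.5
  km3 <- km_estimate(surv_records(c(5, 6, 7, 8), c(1, 0, 0, 0)))$curves[[1]]
  expect_true(is.na(km3$median))
})

test_that("log-rank: identical groups give chi-square 0, labels permute freely", {
  rec <- surv_records(rep(c(2, 5, 9, 14), 2), rep(1, 8))
  g <- rep(c("A", "B"), each = 4)   # identical survival experience
  lr <- logrank_test(rec, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-9)
  set.seed(10)
  rec2 <- surv_records(stats::rexp(30, 0.1), stats::rbinom(30, 1, 0.8))
  g2 <- sample(c("A", "B"), 30, replace = TRUE)
  lr_ab <- logrank_test(rec2, g2)
  lr_ba <- logrank_test(rec2, ifelse(g2 == "A", "B", "A"))
  expect_equal(lr_ab$chisq, lr_ba$chisq, tolerance = 1e-12)
  expect_error(logrank_test(rec2, rep("A", 30)), "groups")
})

test_that("two groups with hazard ratio 2 are separated by the log-rank test", {
  set.seed(11)
  hits <- vapply(1:20, function(s) {
    t1 <- stats::rexp(100, 0.02)
    t2 <- stats::rexp(100, 0.04)
    rec <- surv_records(c(t1, t2), rep(1, 200))
    logrank_test(rec, rep(c("lo", "hi"), each = 100))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("optimized log-rank cutoff finds the only separating split and matches brute force", {
  v <- c(0, 0, 0, 5, 6, 7)
  rec <- surv_records(c(50, 60, 70, 3, 4, 5), rep(1, 6))
  oc <- optimal_logrank_cutoff(v, rec, min_frac = 0.1)
  expect_gt(oc$cutoff, 0 - 1e-12)
  expect_lte(oc$cutoff, 5)
  expect_equal(oc$n_low, 3)
  # brute force over every admissible split on random data
  for (s in 1:3) {
    set.seed(800 + s)
    n <- 30
    vals <- stats::rlnorm(n, 1, 1)
    rec2 <- surv_records(stats::rexp(n, 0.05), stats::rbinom(n, 1, 0.8))
    oc2 <- optimal_logrank_cutoff(vals, rec2)
    sv <- sort(unique(vals))
    cands <- (sv[-1] + sv[-length(sv)]) / 2
    best <- -Inf; best_c <- NA
    for (c0 in cands) {
      hi <- vals > c0
      if (min(sum(hi), sum(!hi)) < ceiling(0.1 * n)) next
      chi <- logrank_test(rec2, ifelse(hi, "h", "l"))$chisq
      if (chi > best) { best <- chi; best_c <- c0 }
    }
    expect_equal(oc2$chisq, best, tolerance = 1e-10)
    expect_equal(oc2$cutoff, best_c)
  }
  # invariance under strictly monotone transforms of the covariate
  set.seed(12)
  vals <- stats::rlnorm(25, 0.5, 1)
  rec3 <- surv_records(stats::rexp(25, 0.05), stats::rbinom(25, 1, 0.8))
  a <- optimal_logrank_cutoff(vals, rec3)
  b <- optimal_logrank_cutoff(log(vals + 1), rec3)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-10)
  expect_setequal(which(vals > a$cutoff), which(log(vals + 1) > b$cutoff))
  expect_error(optimal_logrank_cutoff(rep(1, 10), rec3[1:10, ]), "distinct")
})

test_that("quartile grouping splits 1..8 evenly, flags collapse, balances random data", {
  g <- quartile_groups(1:8)
  expect_equal(as.numeric(table(g)), c(2, 2, 2, 2))
  expect_false(attr(g, "collapsed"))
  expect_warning(g2 <- quartile_groups(rep(3, 10)), "collapsed")
  expect_true(attr(g2, "collapsed"))
  set.seed(13)
  g3 <- quartile_groups(stats::rnorm(50))
  expect_true(all(abs(as.numeric(table(g3)) - 12.5) <= 1))
})

test_that("MTV agreement: identity, log-scale shift, and a known correlation", {
  a <- c(1, 4, 9, 2.5, 7)
  ident <- mtv_agreement(a, a)
  expect_false(ident$applicable)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))
  expect_equal(ident$r_squared, 1)
  # constant shift on the log2(x+1) scale keeps R^2 = 1
  set.seed(14)
  x <- stats::rlnorm(40, 1.5, 1)
  y <- 2 * (x + 1) - 1          # log2p1(y) = log2p1(x) + 1
  sh <- mtv_agreement(y, x)
  expect_equal(sh$r_squared, 1, tolerance = 1e-12)
  expect_lt(sh$wilcoxon_p, 0.001)
  # known correlation 0.95 on the log scale -> R^2 near 0.9025
  set.seed(15)
  n <- 500
  z <- stats::rnorm(n)
  la <- 1.5 + 1.0 * (0.95 * z + sqrt(1 - 0.95^2) * stats::rnorm(n))
  lb <- 1.5 + 1.0 * z
  sim <- mtv_agreement(2^pmax(la, 0) - 1, 2^pmax(lb, 0) - 1)
  expect_equal(sim$r_squared, 0.9025, tolerance = 0.05)
})
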