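# Survival layer: log2(x+1) covariates, Cox PH fits (Efron ties), SPSS-style
# forward likelihood-ratio selection, Gonen-Heller concordance with a
# bootstrap Gauss comparison, Kaplan-Meier / log-rank, quartile and
# optimized log-rank cutoff grouping, and paired MTV agreement statistics.

#' log2(x + 1) transform for volume covariates
#'
#' The doubling-scale transform applied to every MTV covariate before Cox
#' and Pearson regression: 1 ml is added so that 0 ml maps to 0.
#'
#' @param x volumes in ml, `>= 0`.
#' @return `log2(x + 1)`.
#' @export
log2p1 <- function(x) {
  assert_that(all(x >= 0, na.rm = TRUE), "log2p1 requires non-negative input")
  log2(x + 1)
}

build_cox_formula <- function(time, event, covariates) {
  stats::as.formula(
    paste0("survival::Surv(`", time, "`, `", event, "`) ~ ",
           paste0("`", covariates, "`", collapse = " + ")),
    env = environment())
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling (configurable), Wald
#' standard errors from the inverse observed information, hazard ratios
#' `exp(beta)` with 95% Wald intervals. Monotone likelihood (perfect
#' separation) and singular information are reported as errors naming the
#' covariate.
#'
#' @param records survival table (`time_months`, `event`, covariates).
#' @param covariates covariate column names entering the linear predictor.
#' @param time,event column names of follow-up time and the 0/1 event flag.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `cox_fit` object: `covariates`, `coefficients`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `loglik` (null, fitted), `n`, `nevent`,
#'   and the underlying `survival::coxph` fit as `model`.
#' @export
cox_fit <- function(records, covariates, time = "time_months", event = "event",
                    ties = "efron") {
  missing_cols <- setdiff(c(time, event, covariates), names(records))
  assert_that(length(missing_cols) == 0,
              paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  assert_that(sum(records[[event]]) >= 1, "at least one event is required")
  const <- covariates[vapply(covariates,
                             function(v) stats::sd(records[[v]]) == 0, logical(1))]
  assert_that(length(const) == 0,
              paste("constant covariate(s):", paste(const, collapse = ", ")))
  f <- build_cox_formula(time, event, covariates)
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = records, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      toler.chol = 1e-12,
                                                      iter.max = 50)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop2(paste("singular information; collinear covariate(s):",
                paste(covariates[is.na(beta)], collapse = ", ")))
  se <- sqrt(diag(fit$var))
  if (any(grepl("infinite|converge", warns)) && any(abs(beta) > 15))
    stop2(paste("monotone partial likelihood (perfect separation) for covariate:",
                covariates[which.max(abs(beta))]))
  z <- stats::qnorm(0.975)
  structure(list(covariates = covariates,
                 coefficients = stats::setNames(as.numeric(beta), covariates),
                 se = stats::setNames(as.numeric(se), covariates),
                 hr = exp(as.numeric(beta)),
                 ci_lower = exp(as.numeric(beta) - z * se),
                 ci_upper = exp(as.numeric(beta) + z * se),
                 p = 2 * stats::pnorm(-abs(as.numeric(beta) / se)),
                 loglik = fit$loglik, n = fit$n, nevent = fit$nevent,
                 ties = ties, time = time, event = event, model = fit),
            class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$nevent))
  tab <- data.frame(beta = x$coefficients, se = x$se, HR = x$hr,
                    `CI95 low` = x$ci_lower, `CI95 high` = x$ci_upper,
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
predict.cox_fit <- function(object, newdata = NULL, ...) {
  risk_score(object, newdata)
}

# Linear predictor beta' x on (new) data; centering is irrelevant for every
# use here (concordance, comparison) since only differences enter.
risk_score <- function(fit, records = NULL) {
  if (is.null(records))
    return(as.numeric(fit$model$linear.predictors))
  X <- as.matrix(records[, fit$covariates, drop = FALSE])
  as.numeric(X %*% fit$coefficients)
}

# Incremental score test for adding `candidate` to the model `current`
# (possibly empty): the global score statistic evaluated at
# (beta_hat_current, 0), which reduces to the 1-df adjusted score test.
score_entry_test <- function(records, current, candidate, time, event, ties) {
  f <- build_cox_formula(time, event, c(current, candidate))
  init <- c(if (length(current)) stats::coef(
    survival::coxph(build_cox_formula(time, event, current),
                    data = records, ties = ties)) else NULL, 0)
  fit <- suppressWarnings(
    survival::coxph(f, data = records, ties = ties, init = init,
                    control = survival::coxph.control(iter.max = 0)))
  stat <- as.numeric(fit$score)
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Forward likelihood-ratio stepwise Cox regression
#'
#' The SPSS "forward LR" procedure with its standard settings: candidate
#' entry by the score test at `alpha_entry = 0.05`, removal of included
#' covariates by the likelihood-ratio test at `alpha_remove = 0.10`,
#' iterated until no further change. The trace records every tested entry
#' and removal with its statistic.
#'
#' @param records survival table.
#' @param candidates candidate covariate column names (>= 2).
#' @param time,event,ties as in [cox_fit()].
#' @param alpha_entry,alpha_remove entry and removal thresholds.
#' @return `stepwise_cox` object: `fit` (a [cox_fit()], or `NULL` for the
#'   empty model), `selected`, `trace` (`data.frame`).
#' @export
stepwise_cox <- function(records, candidates, time = "time_months",
                         event = "event", ties = "efron",
                         alpha_entry = 0.05, alpha_remove = 0.10) {
  assert_that(length(candidates) >= 2, "need >= 2 candidate covariates")
  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      covariate = character(0), statistic = numeric(0),
                      p = numeric(0), included = character(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    tests <- vapply(pool, function(v)
      score_entry_test(records, selected, v, time, event, ties), numeric(2))
    best <- which.min(tests["p", ])
    step <- step + 1L
    entered <- tests["p", best] < alpha_entry
    trace <- rbind(trace, data.frame(
      step = step, action = if (entered) "enter" else "entry rejected",
      covariate = pool[best], statistic = tests["stat", best],
      p = tests["p", best],
      included = paste(c(selected, if (entered) pool[best]), collapse = "+"),
      stringsAsFactors = FALSE))
    if (!entered) break
    selected <- c(selected, pool[best])
    # backward LR sweep over the included set
    repeat {
      if (length(selected) < 2) break
      ll_full <- cox_fit(records, selected, time, event, ties)$loglik[2]
      lr <- vapply(selected, function(v) {
        ll0 <- cox_fit(records, setdiff(selected, v), time, event, ties)$loglik[2]
        stat <- 2 * (ll_full - ll0)
        c(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
      }, numeric(2))
      worst <- which.max(lr["p", ])
      if (lr["p", worst] <= alpha_remove) break
      # never remove the covariate just entered (prevents entry/removal cycles)
      if (selected[worst] == selected[length(selected)]) break
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, action = "remove", covariate = selected[worst],
        statistic = lr["stat", worst], p = lr["p", worst],
        included = paste(setdiff(selected, selected[worst]), collapse = "+"),
        stringsAsFactors = FALSE))
      selected <- setdiff(selected, selected[worst])
    }
  }
  structure(list(fit = if (length(selected))
    cox_fit(records, selected, time, event, ties) else NULL,
    selected = selected, trace = trace,
    alpha_entry = alpha_entry, alpha_remove = alpha_remove),
    class = "stepwise_cox")
}

#' @export
print.stepwise_cox <- function(x, ...) {
  cat(sprintf("Forward-LR stepwise Cox (entry %.2f / removal %.2f)\n",
              x$alpha_entry, x$alpha_remove))
  print(x$trace, digits = 4)
  if (is.null(x$fit)) cat("Final model: empty\n") else print(x$fit)
  invisible(x)
}

#' Gonen-Heller concordance probability estimate
#'
#' The censoring-free concordance probability of a fitted Cox model,
#' computed from pairwise differences of the risk scores only: each
#' unordered pair contributes `1 / (1 + exp(-|eta_i - eta_j|))`; tied scores
#' contribute 1/2. A null model (all scores identical) returns 0.5 with a
#' degeneracy flag. Unsmoothed estimator.
#'
#' @param fit a [cox_fit()], or a numeric vector of risk scores.
#' @param records optional data on which to evaluate the risk scores
#'   (defaults to the fitting data).
#' @return Concordance in `[0.5, 1)`; attribute `degenerate` is `TRUE` when
#'   all risk scores coincide.
#' @export
gonen_heller_cpe <- function(fit, records = NULL) {
  eta <- if (is.numeric(fit)) fit else risk_score(fit, records)
  n <- length(eta)
  assert_that(n >= 2, "concordance needs >= 2 subjects")
  if (max(eta) == min(eta))
    return(structure(0.5, degenerate = TRUE))
  d <- abs(outer(eta, eta, "-"))
  k <- (sum(1 / (1 + exp(-d))) - 0.5 * n) / (n * (n - 1))
  structure(k, degenerate = FALSE)
}

#' Bootstrap Gauss test comparing two models' concordance
#'
#' Paired patient-level bootstrap: each replicate resamples patients with
#' replacement, refits both models, and records the difference of their
#' Gonen-Heller concordances; `z = mean(delta) / SD(delta)` is referred to
#' the standard normal (two-sided). Replicates where either refit fails are
#' dropped and counted; more than 20% dropped is an error. A degenerate SD
#' of 0 (e.g. a model compared with itself) returns p = 1.
#'
#' @param records survival table.
#' @param covariates_a,covariates_b covariate sets of the two models.
#' @param time,event,ties as in [cox_fit()].
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return `cpe_comparison` list: `cpe_a`, `cpe_b`, `delta`, `z`, `p`,
#'   `B_used`, `B_dropped`.
#' @export
compare_cpe_bootstrap <- function(records, covariates_a, covariates_b,
                                  time = "time_months", event = "event",
                                  ties = "efron", B = 1000, seed = NULL) {
  fit_a <- cox_fit(records, covariates_a, time, event, ties)
  fit_b <- cox_fit(records, covariates_b, time, event, ties)
  cpe_a <- as.numeric(gonen_heller_cpe(fit_a))
  cpe_b <- as.numeric(gonen_heller_cpe(fit_b))
  n <- nrow(records)
  Xa <- as.matrix(records[, covariates_a, drop = FALSE])
  Xb <- as.matrix(records[, covariates_b, drop = FALSE])
  y <- survival::Surv(records[[time]], records[[event]])
  # replicate refits go through the bare coxph engine (no formula/model
  # frame overhead); identical estimator to cox_fit
  refit_cpe <- function(X, idx) {
    f <- survival::coxph.fit(X[idx, , drop = FALSE], y[idx, , drop = FALSE],
                             strata = NULL, offset = NULL,
                             init = rep(0, ncol(X)),
                             control = survival::coxph.control(eps = 1e-9,
                                                               iter.max = 50),
                             weights = NULL, method = ties, rownames = NULL)
    beta <- f$coefficients
    if (any(!is.finite(beta)) || any(abs(beta) > 15)) return(NA_real_)
    as.numeric(gonen_heller_cpe(as.numeric(X[idx, , drop = FALSE] %*% beta)))
  }
  deltas <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(refit_cpe(Xa, idx) - refit_cpe(Xb, idx),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- is.finite(deltas)
  assert_that(mean(!ok) <= 0.2,
              sprintf("%.0f%% of bootstrap replicates failed to converge",
                      100 * mean(!ok)))
  d <- deltas[ok]
  s <- stats::sd(d)
  z <- if (is.na(s) || s == 0) 0 else mean(d) / s
  p <- if (z == 0 && s == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(cpe_a = cpe_a, cpe_b = cpe_b, delta = cpe_a - cpe_b,
                 z = z, p = p, B_used = sum(ok), B_dropped = sum(!ok)),
            class = "cpe_comparison")
}

#' @export
print.cpe_comparison <- function(x, ...) {
  cat(sprintf("Concordance %.3f vs %.3f (delta %.4f); bootstrap Gauss z = %.2f, p = %.3g (%d replicates%s)\n",
              x$cpe_a, x$cpe_b, x$delta, x$z, x$p, x$B_used,
              if (x$B_dropped) sprintf(", %d dropped", x$B_dropped) else ""))
  invisible(x)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator; the reported median is the earliest time at
#' which survival drops to 0.5 or below, undefined (`NA`) when the curve
#' never does.
#'
#' @param records survival table.
#' @param groups group label per patient (`NULL` = one group).
#' @param time,event column names.
#' @return `km_curves`: list of per-group curves (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `median`) plus the underlying
#'   `survival::survfit`.
#' @export
km_estimate <- function(records, groups = NULL, time = "time_months",
                        event = "event") {
  g <- if (is.null(groups)) factor(rep("all", nrow(records))) else factor(groups)
  assert_that(all(table(g) >= 1) && !any(is.na(g)), "each group needs >= 1 subject")
  dat <- data.frame(.time = records[[time]], .event = records[[event]], .g = g)
  sf <- survival::survfit(survival::Surv(.time, .event) ~ .g, data = dat)
  strata <- if (is.null(sf$strata)) stats::setNames(length(sf$time), levels(g)[1])
            else sf$strata
  idx <- rep(seq_along(strata), strata)
  nms <- sub("^\\.g=", "", names(strata))
  curves <- lapply(seq_along(strata), function(i) {
    sel <- idx == i
    s <- sf$surv[sel]
    t <- sf$time[sel]
    med <- if (any(s <= 0.5)) t[which(s <= 0.5)[1]] else NA_real_
    list(group = nms[i], time = t, n_risk = sf$n.risk[sel],
         n_event = sf$n.event[sel], n_censor = sf$n.censor[sel],
         surv = s, median = med)
  })
  names(curves) <- nms
  structure(list(curves = curves, survfit = sf), class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  for (cv in x$curves)
    cat(sprintf("%s: n events %d, median OS %s months\n", cv$group,
                sum(cv$n_event),
                if (is.na(cv$median)) "not reached" else format(cv$median, digits = 4)))
  invisible(x)
}

#' @export
plot.km_curves <- function(x, ...) {
  graphics::plot(x$survfit, xlab = "Months", ylab = "Survival probability", ...)
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic across groups.
#'
#' @param records survival table.
#' @param groups group label per patient.
#' @param time,event column names.
#' @return List `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records, groups, time = "time_months", event = "event") {
  g <- factor(groups)
  g <- droplevels(g)
  assert_that(nlevels(g) >= 2, "log-rank needs >= 2 non-empty groups")
  dat <- data.frame(.time = records[[time]], .event = records[[event]], .g = g)
  sd_ <- survival::survdiff(survival::Surv(.time, .event) ~ .g, data = dat)
  df <- nlevels(g) - 1
  chisq <- as.numeric(sd_$chisq)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Optimized log-rank cutoff for a continuous covariate
#'
#' Scans every midpoint between consecutive sorted distinct values
#' (including the 0-vs-positive split when zeros are present), subject to a
#' minimum arm size, and returns the cutoff maximizing the log-rank
#' chi-square. The returned p-value is the naive chi-square p and is
#' selection-inflated; it is labelled accordingly and should not be read as
#' a calibrated test.
#'
#' @param values per-patient covariate (e.g. organ MTV, ml).
#' @param records survival table aligned with `values`.
#' @param min_frac minimum fraction of patients per arm (default 0.10).
#' @param time,event column names.
#' @return `logrank_cutoff` list: `cutoff`, `chisq`, `p_naive`, `n_low`,
#'   `n_high`, and the full `scan` table.
#' @export
optimal_logrank_cutoff <- function(values, records, min_frac = 0.10,
                                   time = "time_months", event = "event") {
  assert_that(length(values) == nrow(records),
              "values and records must be aligned")
  v <- sort(unique(values))
  assert_that(length(v) >= 2, "need >= 2 distinct covariate values")
  cand <- (v[-1] + v[-length(v)]) / 2
  if (any(values == 0) && any(values > 0)) cand <- sort(unique(c(0, cand)))
  n <- length(values)
  min_arm <- ceiling(min_frac * n)
  scan <- NULL
  for (c0 in cand) {
    hi <- values > c0
    if (sum(hi) < min_arm || sum(!hi) < min_arm) next
    lr <- logrank_test(records, ifelse(hi, "high", "low"), time, event)
    scan <- rbind(scan, data.frame(cutoff = c0, chisq = lr$chisq,
                                   n_low = sum(!hi), n_high = sum(hi)))
  }
  assert_that(!is.null(scan), "no admissible split satisfies the arm-size floor")
  best <- scan[which.max(scan$chisq), ]
  structure(list(cutoff = best$cutoff, chisq = best$chisq,
                 p_naive = stats::pchisq(best$chisq, 1, lower.tail = FALSE),
                 n_low = best$n_low, n_high = best$n_high, scan = scan),
            class = "logrank_cutoff")
}

#' @export
print.logrank_cutoff <- function(x, ...) {
  cat(sprintf("Optimized log-rank cutoff: %.3g (chisq %.2f, naive p %.3g; n %d vs %d)\n",
              x$cutoff, x$chisq, x$p_naive, x$n_low, x$n_high))
  cat("Note: the p-value is selection-inflated (maximally selected statistic).\n")
  invisible(x)
}

#' Quartile groups of a covariate
#'
#' Groups at the 25/50/75th percentiles (linear-interpolation quantiles,
#' type 7); ties are assigned to the lower group. When fewer distinct
#' values than groups exist, collapsed groups are flagged via the
#' `collapsed` attribute.
#'
#' @param values numeric vector, `n >= 4`.
#' @return Factor `Q1`-`Q4` with attribute `collapsed`.
#' @export
quartile_groups <- function(values) {
  assert_that(length(values) >= 4, "quartile grouping needs n >= 4")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  g <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  f <- factor(paste0("Q", g), levels = paste0("Q", 1:4))
  collapsed <- nlevels(droplevels(f)) < 4
  if (collapsed)
    warning("quartile boundaries coincide; groups collapsed")
  attr(f, "collapsed") <- collapsed
  f
}

#' Agreement between two paired MTV measurements
#'
#' Wilcoxon signed-rank test on the raw paired differences (zero
#' differences dropped; exact for small samples, normal approximation with
#' tie correction otherwise), squared Pearson correlation on the
#' log2(x + 1) scale, and Bland-Altman bias with 95% limits of agreement
#' (`bias +- 1.96 * SD` of the differences `a - b`).
#'
#' @param a,b paired per-patient MTV vectors (same patients, `n >= 3`).
#' @return `mtv_agreement` list: `wilcoxon_p`, `wilcoxon_V`, `r_squared`
#'   (log2 scale), `bias`, `loa_lower`, `loa_upper`, `n`, `applicable`.
#' @export
mtv_agreement <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 3,
              "paired vectors of equal length >= 3 required")
  d <- a - b
  identical_pairs <- all(d == 0)
  wil <- if (identical_pairs) list(statistic = NA_real_, p.value = NA_real_)
  else suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE,
                       exact = sum(d != 0) <= 25, correct = FALSE))
  la <- log2p1(a); lb <- log2p1(b)
  r2 <- if (stats::sd(la) == 0 || stats::sd(lb) == 0) NA_real_
        else stats::cor(la, lb)^2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(wilcoxon_p = wil$p.value,
                 wilcoxon_V = as.numeric(wil$statistic),
                 r_squared = r2, bias = bias,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = length(a), applicable = !identical_pairs),
            class = "mtv_agreement")
}

#' @export
print.mtv_agreement <- function(x, ...) {
  cat(sprintf("Paired MTV agreement (n = %d):\n", x$n))
  if (x$applicable)
    cat(sprintf("  Wilcoxon signed-rank p = %.3g\n", x$wilcoxon_p))
  else cat("  Wilcoxon signed-rank: not applicable (all pairs identical)\n")
  cat(sprintf("  R^2 (log2 scale) = %s\n",
              if (is.na(x$r_squared)) "undefined" else sprintf("%.3f", x$r_squared)))
  cat(sprintf("  Bland-Altman bias %.3f ml, 95%% LoA [%.3f, %.3f]\n",
              x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}
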