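# Candidate-vs-reference evaluation: focus matching, classification metrics
# at per-focus and per-patient scope, patient-level bootstrap CIs,
# anatomical-label accuracy, and missed-lesion characterization.

pf_key <- function(p, f) paste(p, f, sep = "\r")

#' Match a candidate read against the reference read
#'
#' Pairs foci by `(patient_id, focus_id)` when the candidate read was
#' produced on the same detection set (the [simulate_detector()] path), or
#' by maximal voxel overlap when per-focus masks are supplied. The status of
#' each row follows the classification pair: TP = both suspicious, TN = both
#' unsuspicious, FN = reference suspicious but candidate unsuspicious or
#' absent, FP = candidate suspicious but reference unsuspicious or absent.
#' A candidate focus overlapping two reference foci equally is assigned to
#' the reference focus with the higher SUVmax.
#'
#' @param reference,candidate lesion tables covering the same patients.
#' @param ref_masks,cand_masks optional named lists (names =
#'   `paste(patient_id, focus_id, sep = ":")`) of linear voxel index
#'   vectors; when both are given, pairing is by maximal overlap.
#' @return `match_table` data.frame: one row per reference focus plus one
#'   per unpaired candidate focus, with classifications, `status`,
#'   `measurable`, and per-level label agreement flags.
#' @export
match_foci <- function(reference, candidate, ref_masks = NULL, cand_masks = NULL) {
  assert_that(all(candidate$patient_id %in% reference$patient_id),
              "candidate read contains patients absent from the reference")
  use_masks <- !is.null(ref_masks) && !is.null(cand_masks)

  if (use_masks) {
    pairs <- overlap_pairs(reference, candidate, ref_masks, cand_masks)
  } else {
    pairs <- data.frame(ref_key = pf_key(reference$patient_id, reference$focus_id),
                        cand_key = pf_key(reference$patient_id, reference$focus_id),
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$cand_key %in% pf_key(candidate$patient_id, candidate$focus_id), ]
  }

  rkey <- pf_key(reference$patient_id, reference$focus_id)
  ckey <- pf_key(candidate$patient_id, candidate$focus_id)
  ref_to_cand <- pairs$cand_key[match(rkey, pairs$ref_key)]
  ci <- match(ref_to_cand, ckey)

  cand_class <- ifelse(is.na(ci), NA_character_, candidate$classification[ci])
  status <- ifelse(reference$classification == "suspicious",
                   ifelse(!is.na(cand_class) & cand_class == "suspicious", "TP", "FN"),
                   ifelse(!is.na(cand_class) & cand_class == "suspicious", "FP", "TN"))

  lab_eq <- function(a, b) ifelse(is.na(ci), NA, !is.na(b) & !is.na(a) & a == b)
  m_bp <- lab_eq(reference$body_part, candidate$body_part[ci])
  m_rg <- lab_eq(reference$region, candidate$region[ci])
  has_sub <- !is.na(reference$subregion)
  m_sr <- ifelse(has_sub, lab_eq(reference$subregion, candidate$subregion[ci]), NA)
  m_md <- ifelse(has_sub, m_sr, m_rg)

  out <- data.frame(
    patient_id = reference$patient_id,
    ref_focus_id = reference$focus_id,
    cand_focus_id = ifelse(is.na(ci), NA_character_, candidate$focus_id[ci]),
    ref_class = reference$classification,
    cand_class = cand_class,
    status = status,
    measurable = if ("measurable" %in% names(reference))
      as.logical(reference$measurable) else NA,
    has_subregion = has_sub,
    match_body_part = m_bp, match_region = m_rg,
    match_subregion = m_sr, match_most_detailed = m_md,
    stringsAsFactors = FALSE)

  # unpaired candidate foci: FP when flagged suspicious, TN otherwise
  extra <- which(!(ckey %in% pairs$cand_key))
  if (length(extra) > 0) {
    out <- rbind(out, data.frame(
      patient_id = candidate$patient_id[extra],
      ref_focus_id = NA_character_,
      cand_focus_id = candidate$focus_id[extra],
      ref_class = NA_character_,
      cand_class = candidate$classification[extra],
      status = ifelse(candidate$classification[extra] == "suspicious", "FP", "TN"),
      measurable = if ("measurable" %in% names(candidate))
        as.logical(candidate$measurable[extra]) else NA,
      has_subregion = FALSE,
      match_body_part = NA, match_region = NA,
      match_subregion = NA, match_most_detailed = NA,
      stringsAsFactors = FALSE))
  }
  class(out) <- c("match_table", class(out))
  out
}

# Greedy maximal-overlap pairing within each patient; equal overlaps break
# toward the reference focus with higher SUVmax.
overlap_pairs <- function(reference, candidate, ref_masks, cand_masks) {
  res <- list()
  for (p in unique(reference$patient_id)) {
    ref_p <- reference[reference$patient_id == p, , drop = FALSE]
    cand_p <- candidate[candidate$patient_id == p, , drop = FALSE]
    if (nrow(ref_p) == 0 || nrow(cand_p) == 0) next
    cand_entries <- NULL
    for (a in seq_len(nrow(cand_p))) {
      cm <- cand_masks[[paste(p, cand_p$focus_id[a], sep = ":")]]
      for (b in seq_len(nrow(ref_p))) {
        rm <- ref_masks[[paste(p, ref_p$focus_id[b], sep = ":")]]
        ov <- length(intersect(cm, rm))
        if (ov > 0)
          cand_entries <- rbind(cand_entries,
                                data.frame(a = a, b = b, ov = ov,
                                           suv = ref_p$suvmax[b]))
      }
    }
    if (is.null(cand_entries)) next
    cand_entries <- cand_entries[order(-cand_entries$ov, -cand_entries$suv), ]
    used_a <- used_b <- integer(0)
    for (r in seq_len(nrow(cand_entries))) {
      a <- cand_entries$a[r]; b <- cand_entries$b[r]
      if (a %in% used_a || b %in% used_b) next
      used_a <- c(used_a, a); used_b <- c(used_b, b)
      res[[length(res) + 1]] <- data.frame(
        ref_key = pf_key(p, ref_p$focus_id[b]),
        cand_key = pf_key(p, cand_p$focus_id[a]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    data.frame(ref_key = character(0), cand_key = character(0))
  else do.call(rbind, res)
}

metric_names <- c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                  "label_body_part", "label_region", "label_subregion",
                  "label_most_detailed")

# Per-patient numerator/denominator pairs for a metric. A patient whose
# denominator is 0 carries no information for that metric.
metric_components <- function(matches, metric, measurable_only = FALSE) {
  assert_that(metric %in% metric_names,
              paste("unknown metric:", metric))
  m <- matches
  if (measurable_only) m <- m[!is.na(m$measurable) & m$measurable, , drop = FALSE]
  assert_that(nrow(m) > 0, "no foci in scope")
  tp <- m$status == "TP"; fn <- m$status == "FN"
  tn <- m$status == "TN"; fp <- m$status == "FP"
  nd <- switch(metric,
    sensitivity = list(num = tp, den = tp | fn),
    specificity = list(num = tn, den = tn | fp),
    accuracy    = list(num = tp | tn, den = rep(TRUE, nrow(m))),
    ppv         = list(num = tp, den = tp | fp),
    npv         = list(num = tn, den = tn | fn),
    label_body_part = list(num = m$match_body_part %in% TRUE,
                           den = !is.na(m$match_body_part)),
    label_region = list(num = m$match_region %in% TRUE,
                        den = !is.na(m$match_region)),
    label_subregion = list(num = m$match_subregion %in% TRUE,
                           den = !is.na(m$match_subregion)),
    label_most_detailed = list(num = m$match_most_detailed %in% TRUE,
                               den = !is.na(m$match_most_detailed)))
  pid <- factor(m$patient_id)
  data.frame(patient_id = levels(pid),
             num = as.numeric(tapply(nd$num, pid, sum)),
             den = as.numeric(tapply(nd$den, pid, sum)),
             stringsAsFactors = FALSE)
}

pooled_estimate <- function(comp, scope) {
  if (scope == "per_focus") {
    if (sum(comp$den) == 0) return(NA_real_)
    sum(comp$num) / sum(comp$den)
  } else {
    r <- comp$num[comp$den > 0] / comp$den[comp$den > 0]
    if (length(r) == 0) return(NA_real_)
    mean(r)
  }
}

#' Classification metrics of a match table
#'
#' Point estimates of sensitivity, specificity, accuracy, PPV and NPV.
#' Per-focus scope pools all foci; per-patient scope computes each metric
#' within each patient and averages over the patients for which it is
#' defined (patients with an empty denominator are excluded, and their count
#' reported).
#'
#' @param matches a [match_foci()] table.
#' @param scope `"per_focus"` or `"per_patient"`.
#' @param measurable_only restrict to PERCIST-measurable foci first.
#' @param metrics metric names to compute.
#' @return `data.frame` with `name`, `scope`, `estimate`, `n_patients_used`.
#' @export
classification_metrics <- function(matches, scope = c("per_focus", "per_patient"),
                                   measurable_only = FALSE,
                                   metrics = c("sensitivity", "specificity",
                                               "accuracy", "ppv", "npv")) {
  scope <- match.arg(scope)
  rows <- lapply(metrics, function(met) {
    comp <- metric_components(matches, met, measurable_only)
    est <- pooled_estimate(comp, scope)
    if (is.na(est))
      stop2(sprintf("metric '%s' is undefined for every patient", met))
    data.frame(name = met, scope = scope, estimate = est,
               n_patients_used = sum(comp$den > 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Patient-level bootstrap confidence interval for a metric
#'
#' Resamples patients with replacement (each drawn patient carries all its
#' foci), recomputes the metric per replicate, and returns the percentile
#' interval. Replicates where the metric is undefined are dropped and
#' counted. Deterministic for a fixed seed.
#'
#' @param matches a [match_foci()] table with >= 2 patients.
#' @param metric one of sensitivity, specificity, accuracy, ppv, npv,
#'   label_body_part, label_region, label_subregion, label_most_detailed.
#' @param scope `"per_focus"` or `"per_patient"`.
#' @param measurable_only restrict to measurable foci.
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return `metric_ci` object: `name`, `scope`, `estimate`, `lower`,
#'   `upper`, `level`, `B`, `B_dropped`.
#' @export
bootstrap_ci <- function(matches, metric, scope = c("per_focus", "per_patient"),
                         measurable_only = FALSE, B = 1000, level = 0.95,
                         seed = NULL) {
  scope <- match.arg(scope)
  comp <- metric_components(matches, metric, measurable_only)
  n_pat <- nrow(comp)
  assert_that(n_pat >= 2, "bootstrap requires >= 2 patients")
  est <- pooled_estimate(comp, scope)
  if (is.na(est)) stop2(sprintf("metric '%s' undefined on the full data", metric))
  stats <- with_seed(seed, {
    draws <- matrix(sample.int(n_pat, n_pat * B, replace = TRUE), nrow = B)
    if (scope == "per_focus") {
      num <- matrix(comp$num[draws], nrow = B)
      den <- matrix(comp$den[draws], nrow = B)
      rowSums(num) / rowSums(den)  # NaN when denominator 0
    } else {
      ratio <- ifelse(comp$den > 0, comp$num / comp$den, NA_real_)
      r <- matrix(ratio[draws], nrow = B)
      rowMeans(r, na.rm = TRUE)    # NaN when every patient undefined
    }
  })
  ok <- is.finite(stats)
  assert_that(any(ok), "metric undefined in every bootstrap replicate")
  alpha <- (1 - level) / 2
  qs <- stats::quantile(stats[ok], c(alpha, 1 - alpha), names = FALSE)
  structure(list(name = metric, scope = scope, estimate = est,
                 lower = qs[1], upper = qs[2], level = level,
                 B = sum(ok), B_dropped = sum(!ok)),
            class = "metric_ci")
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(sprintf("%s (%s): %.3f (%.0f%% CI %.3f-%.3f; %d replicates%s)\n",
              x$name, x$scope, x$estimate, 100 * x$level, x$lower, x$upper,
              x$B, if (x$B_dropped > 0)
                sprintf(", %d dropped", x$B_dropped) else ""))
  invisible(x)
}

#' Anatomical label accuracy
#'
#' Fraction of matched foci whose candidate label equals the reference label
#' at the requested granularity. Subregion accuracy is computed only over
#' foci whose reference provides a subregion; the most-detailed level
#' compares at the finest reference-provided level per focus (subregion when
#' present, region otherwise).
#'
#' @param matches a [match_foci()] table.
#' @param level `"body_part"`, `"region"`, `"subregion"`, `"most_detailed"`.
#' @param scope `"per_focus"` or `"per_patient"`.
#' @param B bootstrap replicates for the CI; `NULL` for the point estimate
#'   only.
#' @param seed,level_ci bootstrap seed and confidence level.
#' @return `metric_ci` object (CI fields `NA` when `B` is `NULL`).
#' @export
label_accuracy <- function(matches, level = c("body_part", "region",
                                              "subregion", "most_detailed"),
                           scope = c("per_focus", "per_patient"),
                           B = NULL, seed = NULL, level_ci = 0.95) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  metric <- paste0("label_", level)
  comp <- metric_components(matches, metric)
  assert_that(sum(comp$den) > 0,
              sprintf("no focus carries a %s label on both sides", level))
  if (!is.null(B))
    return(bootstrap_ci(matches, metric, scope, B = B, seed = seed,
                        level = level_ci))
  est <- pooled_estimate(comp, scope)
  structure(list(name = metric, scope = scope, estimate = est,
                 lower = NA_real_, upper = NA_real_, level = level_ci,
                 B = 0L, B_dropped = 0L),
            class = "metric_ci")
}

#' Compare missed and detected suspicious foci
#'
#' Contrasts MTV and SUVmax of reference-suspicious foci the candidate
#' missed (FN) against those it found (TP), with two-sided Mann-Whitney U
#' tests (exact for small samples, normal approximation with tie correction
#' otherwise).
#'
#' @param matches a [match_foci()] table.
#' @param reference the reference lesion table (source of MTV / SUVmax).
#' @return `missed_lesion_report` list with group summaries, U statistics
#'   and p-values; `applicable = FALSE` when either group is empty.
#' @export
missed_lesion_comparison <- function(matches, reference) {
  key <- pf_key(reference$patient_id, reference$focus_id)
  mk <- pf_key(matches$patient_id, matches$ref_focus_id)
  i <- match(mk, key)
  vol <- reference$volume_ml[i]
  suv <- reference$suvmax[i]
  fn <- matches$status == "FN"
  tp <- matches$status == "TP"
  if (!any(fn) || !any(tp)) {
    return(structure(list(applicable = FALSE, n_missed = sum(fn),
                          n_detected = sum(tp)),
                     class = "missed_lesion_report"))
  }
  one <- function(x_fn, x_tp) {
    wt <- suppressWarnings(
      stats::wilcox.test(x_fn, x_tp, exact = (length(x_fn) <= 20 &&
                                              length(x_tp) <= 20),
                         correct = FALSE))
    list(missed_mean = mean(x_fn), detected_mean = mean(x_tp),
         missed_median = stats::median(x_fn),
         detected_median = stats::median(x_tp),
         U = unname(wt$statistic), p = wt$p.value)
  }
  structure(list(applicable = TRUE, n_missed = sum(fn), n_detected = sum(tp),
                 mtv = one(vol[fn], vol[tp]),
                 suvmax = one(suv[fn], suv[tp])),
            class = "missed_lesion_report")
}

#' @export
print.missed_lesion_report <- function(x, ...) {
  if (!x$applicable) {
    cat("Missed-lesion comparison not applicable (a group is empty).\n")
    return(invisible(x))
  }
  cat(sprintf("Missed (n=%d) vs detected (n=%d) suspicious foci:\n",
              x$n_missed, x$n_detected))
  cat(sprintf("  MTV:    %.2f vs %.2f ml (means; U = %.1f, p = %.3g)\n",
              x$mtv$missed_mean, x$mtv$detected_mean, x$mtv$U, x$mtv$p))
  cat(sprintf("  SUVmax: %.2f vs %.2f (means; U = %.1f, p = %.3g)\n",
              x$suvmax$missed_mean, x$suvmax$detected_mean, x$suvmax$U,
              x$suvmax$p))
  invisible(x)
}
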