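# End-to-end driver: phantom -> reference quantification -> simulated
# candidate read -> detection evaluation -> survival layer, under one YAML
# config with explicit per-stage seeds, writing tables, metric reports and a
# manifest. Reruns with the same config reproduce all stochastic outputs.

#' Default pipeline configuration
#'
#' A small, fully seeded end-to-end run. Stage seeds are mandatory: the
#' pipeline has four stochastic stages (phantom, detector, bootstrap,
#' cohort) that must be independently reproducible.
#'
#' @param output_dir output directory.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(output_dir = "petmtv_run") {
  list(
    output_dir = output_dir,
    phantom = list(seed = 101, n_patients = 3, grid_dim = c(96, 96, 128),
                   blur_fwhm_mm = 0),
    detector = list(seed = 202),
    evaluation = list(seed = 303, bootstrap = 200, level = 0.95),
    cohort = list(seed = 404, n_patients = 50, bootstrap = 200)
  )
}

require_seed <- function(cfg, stage) {
  s <- cfg[[stage]]$seed
  assert_that(!is.null(s) && is.finite(s),
              sprintf("config stage '%s' lacks an explicit seed", stage))
  as.integer(s)
}

# Reference read of one phantom: detected foci get the classification and
# labels of the truth lesion whose centre they contain; truth lesions the
# thresholding pipeline missed are added manually (at their true volume,
# as an expert reader would), flagged in the `added` column.
reference_read <- function(ph, quant, patient_id) {
  truth <- ph$lesions
  dims <- dim(ph$volume$data)
  lv_stats <- quant$liver_stats
  rows <- list()
  matched_truth <- character(0)
  for (f in quant$foci) {
    hit <- NA_integer_
    if (nrow(truth) > 0) {
      ctr_lin <- coord_to_linear(cbind(round(truth$cx), round(truth$cy),
                                       round(truth$cz)), dims)
      w <- which(ctr_lin %in% f$voxels)
      if (length(w) > 0) hit <- w[1]
    }
    if (!is.na(hit)) {
      matched_truth <- c(matched_truth, truth$focus_id[hit])
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patient_id, focus_id = truth$focus_id[hit],
        body_part = truth$body_part[hit], region = truth$region[hit],
        subregion = truth$subregion[hit], volume_ml = f$mtv_ml,
        suvmax = f$suvmax, suvpeak = f$suvpeak, measurable = f$measurable,
        classification = truth$classification[hit], added = FALSE,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patient_id, focus_id = paste0("X", f$focus_id),
        body_part = "thorax", region = "soft tissue",
        subregion = NA_character_, volume_ml = f$mtv_ml,
        suvmax = f$suvmax, suvpeak = f$suvpeak, measurable = f$measurable,
        classification = "unsuspicious", added = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  missed <- setdiff(truth$focus_id, matched_truth)
  for (id in missed) {
    i <- which(truth$focus_id == id)
    vox <- ph$lesion_voxels[[id]]
    pk <- suv_peak(ph$volume, vox)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = patient_id, focus_id = id,
      body_part = truth$body_part[i], region = truth$region[i],
      subregion = truth$subregion[i],
      volume_ml = truth$volume_ml[i], suvmax = truth$suvmax[i],
      suvpeak = pk, measurable = percist_measurable(pk, lv_stats),
      classification = truth$classification[i], added = TRUE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes phantom generation, reference quantification, the simulated
#' candidate read, detection evaluation with patient-level bootstrap CIs,
#' and the survival layer, writing lesion tables (CSV), metric and survival
#' reports (JSON), Kaplan-Meier step tables (CSV) and a manifest with the
#' config hash and package version. A stage failure aborts with the stage
#' name; already-written outputs are listed in the partial manifest.
#'
#' @param config configuration list (see [default_run_config()]) or path to
#'   a YAML file with the same structure. Every stochastic stage must carry
#'   an explicit seed; this is validated before any computation.
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config) && !is.null(config$output_dir),
              "config must be a list (or YAML path) with an output_dir")
  seeds <- c(phantom = require_seed(config, "phantom"),
             detector = require_seed(config, "detector"),
             evaluation = require_seed(config, "evaluation"),
             cohort = require_seed(config, "cohort"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "init"
  report <- list()
  tryCatch({
    cfg_path <- file.path(out, "config.yaml")
    yaml::write_yaml(config, cfg_path)
    written <- c(written, cfg_path)

    stage <- "phantom"
    message("[phantom] generating ", config$phantom$n_patients %||% 3, " patients")
    n_pat <- config$phantom$n_patients %||% 3
    ref_rows <- list()
    for (i in seq_len(n_pat)) {
      pc <- phantom_config(
        grid_dim = config$phantom$grid_dim %||% c(96, 96, 128),
        blur_fwhm_mm = config$phantom$blur_fwhm_mm %||% 0,
        seed = seeds["phantom"] + i - 1L)
      ph <- generate_phantom(pc)
      ph$volume$patient_id <- sprintf("P%03d", i)
      q <- quantify_volume(ph$volume, ph$bloodpool_mask, ph$liver_mask)
      ref_rows[[i]] <- reference_read(ph, q, sprintf("P%03d", i))
    }
    reference <- do.call(rbind, ref_rows)
    ref_path <- file.path(out, "reference_lesions.csv")
    write_lesion_table(reference, ref_path)
    written <- c(written, ref_path)

    stage <- "detector"
    message("[detector] simulating candidate read")
    prof_args <- config$detector[setdiff(names(config$detector), "seed")]
    profile <- do.call(detector_profile, prof_args)
    candidate <- simulate_detector(reference, profile, seed = seeds["detector"])
    cand_path <- file.path(out, "candidate_lesions.csv")
    write_lesion_table(candidate, cand_path)
    written <- c(written, cand_path)

    stage <- "evaluation"
    message("[evaluation] matching and scoring")
    matches <- match_foci(reference, candidate)
    B <- config$evaluation$bootstrap %||% 1000
    lvl <- config$evaluation$level %||% 0.95
    es <- seeds["evaluation"]
    ci_of <- function(metric, scope, measurable_only, k)
      unclass(bootstrap_ci(matches, metric, scope, measurable_only,
                           B = B, level = lvl, seed = es + k))
    metrics <- list(
      all_foci = list(
        per_focus = lapply(stats::setNames(nm = c("sensitivity", "specificity",
                                                  "accuracy", "ppv", "npv")),
                           function(m) ci_of(m, "per_focus", FALSE,
                                             match(m, metric_names))),
        per_patient = lapply(stats::setNames(nm = c("sensitivity", "specificity",
                                                    "accuracy", "ppv", "npv")),
                             function(m) ci_of(m, "per_patient", FALSE,
                                               10 + match(m, metric_names)))),
      measurable_only = list(
        per_focus = lapply(stats::setNames(nm = c("sensitivity", "specificity",
                                                  "accuracy")),
                           function(m) ci_of(m, "per_focus", TRUE,
                                             20 + match(m, metric_names)))),
      labels = lapply(stats::setNames(nm = c("label_body_part", "label_region",
                                             "label_subregion",
                                             "label_most_detailed")),
                      function(m) ci_of(m, "per_focus", FALSE,
                                        30 + match(m, metric_names))),
      missed_lesions = unclass(missed_lesion_comparison(matches, reference)))
    mtv_manual <- aggregate_mtv(reference, "whole_body")
    mtv_ai <- aggregate_mtv(candidate, "whole_body",
                            patients = mtv_manual$patient_id)
    metrics$mtv_agreement <- if (nrow(mtv_manual) >= 3)
      unclass(mtv_agreement(mtv_ai$whole_body, mtv_manual$whole_body))
    else list(applicable = FALSE, note = "needs >= 3 patients")
    met_path <- file.path(out, "detection_metrics.json")
    write_metric_report(metrics, met_path)
    written <- c(written, met_path)

    stage <- "cohort"
    message("[cohort] survival analysis")
    cc <- cohort_config(n_patients = config$cohort$n_patients %||% 50,
                        seed = seeds["cohort"])
    coh <- generate_cohort(cc)
    rec <- coh$records
    fit_wb <- cox_fit(rec, "log2_mtv_whole_body")
    organ_covs <- paste0("log2_mtv_",
                         organ_col(names(cc$organs)))
    sw <- stepwise_cox(rec, organ_covs)
    cpe_wb <- gonen_heller_cpe(fit_wb)
    cmp <- compare_cpe_bootstrap(rec, "log2_mtv_whole_body",
                                 organ_covs[1],
                                 B = config$cohort$bootstrap %||% 200,
                                 seed = seeds["cohort"] + 1L)
    qg <- quartile_groups(rec$mtv_whole_body)
    km_q <- km_estimate(rec, qg)
    lr_q <- logrank_test(rec, qg)
    cutoffs <- lapply(stats::setNames(nm = organ_col(names(cc$organs))),
                      function(org) {
                        oc <- tryCatch(
                          optimal_logrank_cutoff(rec[[paste0("mtv_", org)]], rec),
                          error = function(e) NULL)
                        if (is.null(oc)) NULL
                        else oc[c("cutoff", "chisq", "p_naive", "n_low", "n_high")]
                      })
    km_tab <- do.call(rbind, lapply(km_q$curves, function(cv)
      data.frame(group = cv$group, time = cv$time, n_risk = cv$n_risk,
                 n_event = cv$n_event, n_censor = cv$n_censor, surv = cv$surv)))
    km_path <- file.path(out, "km_quartiles.csv")
    utils::write.csv(km_tab, km_path, row.names = FALSE)
    surv_path <- file.path(out, "survival_report.json")
    surv_report <- list(
      event_fraction = coh$event_fraction,
      cox_whole_body = list(covariate = "log2_mtv_whole_body",
                            beta = unname(fit_wb$coefficients),
                            hr = fit_wb$hr, ci_lower = fit_wb$ci_lower,
                            ci_upper = fit_wb$ci_upper, p = fit_wb$p),
      stepwise_selected = sw$selected,
      stepwise_trace = sw$trace,
      cpe_whole_body = as.numeric(cpe_wb),
      cpe_comparison = unclass(cmp),
      km_quartiles = lapply(km_q$curves, function(cv)
        list(group = cv$group, median = cv$median)),
      logrank_quartiles = lr_q,
      organ_cutoffs = cutoffs)
    write_metric_report(surv_report, surv_path)
    survival_path <- file.path(out, "cohort_survival.csv")
    write_survival_table(rec, survival_path)
    written <- c(written, km_path, surv_path, survival_path)

    stage <- "manifest"
    manifest <- list(
      package = "petmtv",
      version = as.character(utils::packageVersion("petmtv")),
      config_md5 = unname(tools::md5sum(cfg_path)),
      seeds = as.list(seeds),
      files = basename(written))
    man_path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
    report <- list(reference = reference, candidate = candidate,
                   matches = matches, metrics = metrics,
                   survival = surv_report, manifest = manifest)
    invisible(report)
  }, error = function(e) {
    partial <- list(failed_stage = stage, error = conditionMessage(e),
                    files = basename(written))
    jsonlite::write_json(partial, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop2(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
}
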