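# Synthetic ground truth: whole-body SUV phantoms with lesions of known
# volume/SUVmax/organ, an imperfect candidate detector, and survival cohorts
# drawn from a known Cox model on log2(MTV + 1).

#' Phantom configuration
#'
#' Describes a synthetic whole-body SUV volume: a noisy soft-tissue
#' background, box-shaped mediastinal blood-pool and liver compartments, and
#' a set of spherical lesions that is either given explicitly or sampled from
#' a lesion law. Lesions are voxelized spheres (membership by voxel-centre
#' distance on the anisotropic grid); lesion voxels are set exactly to the
#' lesion's SUVmax so the pre-blur maximum equals the requested value.
#'
#' @param grid_dim integer length-3 grid size in voxels.
#' @param spacing voxel spacing in mm; default 3.18 x 3.18 x 5.0.
#' @param background_suv,background_noise_sd soft-tissue background level and
#'   Gaussian noise SD (noise truncated at 0; SUV cannot be negative).
#' @param bloodpool,liver compartment descriptions: list with `center_frac`
#'   (fraction of grid extent), `size_mm`, `suv_mean`, `suv_sd`.
#' @param lesions explicit lesion `data.frame` with columns `volume_ml`,
#'   `suvmax`, `organ`, `classification` (optional `center` columns
#'   `cx, cy, cz` in voxels), or `NULL` to sample from `lesion_law`.
#' @param lesion_law sampling law: Poisson counts of suspicious and
#'   physiological foci, log-normal volume and SUVmax laws, organ assignment
#'   probabilities over bone / lymph node / liver / lung / soft tissue /
#'   breast-pectoral.
#' @param blur_fwhm_mm optional isotropic Gaussian blur FWHM in mm (0 = off).
#' @param seed RNG seed for this stage.
#' @return `phantom_config` list.
#' @export
phantom_config <- function(grid_dim = c(96, 96, 128),
                           spacing = c(3.18, 3.18, 5.0),
                           background_suv = 0.8,
                           background_noise_sd = 0.15,
                           bloodpool = list(center_frac = c(0.50, 0.50, 0.70),
                                            size_mm = c(25, 25, 60),
                                            suv_mean = 1.8, suv_sd = 0.2),
                           liver = list(center_frac = c(0.30, 0.42, 0.48),
                                        size_mm = c(120, 100, 80),
                                        suv_mean = 2.2, suv_sd = 0.25),
                           lesions = NULL,
                           lesion_law = list(n_suspicious_mean = 11,
                                             n_physiological_mean = 10,
                                             volume_meanlog = log(2.5),
                                             volume_sdlog = 1.0,
                                             suvmax_meanlog = log(7),
                                             suvmax_sdlog = 0.35,
                                             suvmax_min = 4,
                                             organ_probs = c("bone" = 0.25,
                                                             "lymph node" = 0.30,
                                                             "liver" = 0.10,
                                                             "lung" = 0.10,
                                                             "soft tissue" = 0.15,
                                                             "breast/pectoral" = 0.10)),
                           blur_fwhm_mm = 0,
                           seed = NULL) {
  assert_that(length(grid_dim) == 3 && all(grid_dim >= 8),
              "grid_dim must be three values >= 8")
  assert_that(all(spacing > 0), "spacing must be strictly positive on all axes")
  assert_that(background_noise_sd >= 0 && background_suv >= 0,
              "background level and noise SD must be non-negative")
  cfg <- list(grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
              background_suv = background_suv,
              background_noise_sd = background_noise_sd,
              bloodpool = bloodpool, liver = liver,
              lesions = lesions, lesion_law = lesion_law,
              blur_fwhm_mm = blur_fwhm_mm, seed = seed)
  class(cfg) <- "phantom_config"
  cfg
}

# Organ system -> anatomical label triple used by the phantom's truth tables.
organ_label_menu <- function() {
  list(
    "bone" = list(body_part = c("thorax", "abdomen", "lower limb"),
                  region = "bones",
                  subregion = c("spine", "ribs", "sternum", "pelvis", "femur")),
    "lymph node" = list(body_part = c("thorax", "abdomen", "neck"),
                        region = "lymph nodes",
                        subregion = c("axillary lymph nodes", "cervical lymph nodes",
                                      "mesenterial lymph nodes", "lymph node station 1")),
    "liver" = list(body_part = "abdomen", region = "liver", subregion = NA_character_),
    "lung" = list(body_part = "thorax", region = "lung", subregion = NA_character_),
    "soft tissue" = list(body_part = c("thorax", "abdomen", "neck"),
                         region = c("muscles", "skin", "spleen"),
                         subregion = NA_character_),
    "breast/pectoral" = list(body_part = "thorax",
                             region = c("breast", "pectoral muscle"),
                             subregion = NA_character_)
  )
}

box_mask_indices <- function(grid_dim, spacing, center_frac, size_mm) {
  ctr <- center_frac * grid_dim
  half_vox <- (size_mm / 2) / spacing
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, ceiling(ctr[a] - half_vox[a]))
    hi <- min(grid_dim[a], floor(ctr[a] + half_vox[a]))
    lo:hi
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  coord_to_linear(g, grid_dim)
}

# Voxel set of a sphere-like lesion of volume_ml centred at `center` (voxel
# coords): exactly ceiling(volume_ml / voxel volume) voxels, nearest to the
# centre first (mm distance; linear index breaks ties), so the achieved
# volume is the requested volume rounded up to whole voxels.
sphere_voxels <- function(center, volume_ml, grid_dim, spacing) {
  vv <- voxel_volume_ml(spacing)
  n_target <- max(1L, ceiling(volume_ml / vv))
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  w0 <- r / spacing + 2
  repeat {
    rng <- lapply(1:3, function(a) {
      seq(max(1L, floor(center[a] - w0[a])), min(grid_dim[a], ceiling(center[a] + w0[a])))
    })
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    if (nrow(g) >= n_target || all(vapply(1:3, function(a)
      rng[[a]][1] == 1L && rng[[a]][length(rng[[a]])] == grid_dim[a], logical(1))))
      break
    w0 <- w0 * 1.5
  }
  d2 <- ((g[, 1] - center[1]) * spacing[1])^2 +
        ((g[, 2] - center[2]) * spacing[2])^2 +
        ((g[, 3] - center[3]) * spacing[3])^2
  ord <- order(d2, coord_to_linear(g, grid_dim))
  g[ord[seq_len(min(n_target, nrow(g)))], , drop = FALSE]
}

# Separable Gaussian blur with edge replication; fwhm in mm, per-axis sigma
# converted to voxels.
gaussian_blur <- function(arr, spacing, fwhm_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / spacing[axis]
    if (sigma_vox < 1e-6) next
    r <- max(1L, ceiling(3 * sigma_vox))
    k <- stats::dnorm(seq(-r, r) / sigma_vox)
    k <- k / sum(k)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = d[axis])
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    f <- f[(r + 1):(r + nrow(m)), , drop = FALSE]
    arr <- aperm(array(as.numeric(f), d[perm]), order(perm))
  }
  arr
}

sample_lesion_specs <- function(law) {
  n_s <- max(1L, stats::rpois(1, law$n_suspicious_mean))
  n_u <- max(1L, stats::rpois(1, law$n_physiological_mean))
  n <- n_s + n_u
  vol <- stats::rlnorm(n, law$volume_meanlog, law$volume_sdlog)
  suv <- pmax(law$suvmax_min, stats::rlnorm(n, law$suvmax_meanlog, law$suvmax_sdlog))
  organ <- sample(names(law$organ_probs), n, replace = TRUE, prob = law$organ_probs)
  data.frame(volume_ml = vol, suvmax = suv, organ = organ,
             classification = c(rep("suspicious", n_s), rep("unsuspicious", n_u)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic SUV phantom
#'
#' Renders background, blood-pool and liver compartments, and lesions onto a
#' 3-D SUV grid. Lesion voxels are set exactly to the lesion SUVmax; noise is
#' applied outside lesions only and truncated at zero. Liver-organ lesions
#' are placed inside the liver compartment, all others outside both
#' compartments; lesions never touch each other (a guard band keeps
#' connected components separable). Placement uses bounded rejection
#' sampling; exhausting the retry budget raises an error naming the lesion.
#'
#' Liver lesions have their SUVmax raised, if needed, to 2.5x the liver mean
#' so the half-maximum contour stays above the surrounding liver uptake.
#'
#' @param config a [phantom_config()]; its `seed` must be set (the generator
#'   is contractually deterministic for a fixed seed).
#' @return List with `volume` ([suv_volume()]), `bloodpool_mask` and
#'   `liver_mask` (logical arrays excluding lesion voxels), `label_map`
#'   (integer array: 1 = blood pool, 2 = liver), `lesions` (ground-truth
#'   `data.frame` with achieved volumes), `lesion_voxels` (list of linear
#'   voxel index vectors keyed by lesion id).
#' @export
generate_phantom <- function(config) {
  assert_that(inherits(config, "phantom_config"), "config must be a phantom_config")
  with_seed(config$seed %||% stop2("phantom_config$seed must be set"), {
    gd <- config$grid_dim
    sp <- config$spacing
    n_vox <- prod(gd)

    vol <- array(config$background_suv, dim = gd)
    if (config$background_noise_sd > 0)
      vol <- vol + stats::rnorm(n_vox, 0, config$background_noise_sd)

    bp_idx <- box_mask_indices(gd, sp, config$bloodpool$center_frac,
                               config$bloodpool$size_mm)
    lv_idx <- box_mask_indices(gd, sp, config$liver$center_frac,
                               config$liver$size_mm)
    # guard band: lesions of other organs keep a margin from the
    # compartments so half-max region growth cannot leak into them
    guard_mm <- 2 * max(sp)
    bp_guard <- box_mask_indices(gd, sp, config$bloodpool$center_frac,
                                 config$bloodpool$size_mm + 2 * guard_mm)
    lv_guard <- box_mask_indices(gd, sp, config$liver$center_frac,
                                 config$liver$size_mm + 2 * guard_mm)
    vol[bp_idx] <- config$bloodpool$suv_mean +
      if (config$bloodpool$suv_sd > 0)
        stats::rnorm(length(bp_idx), 0, config$bloodpool$suv_sd) else 0
    vol[lv_idx] <- config$liver$suv_mean +
      if (config$liver$suv_sd > 0)
        stats::rnorm(length(lv_idx), 0, config$liver$suv_sd) else 0
    vol <- pmax(vol, 0)

    specs <- config$lesions %||% sample_lesion_specs(config$lesion_law)
    menu <- organ_label_menu()
    lesion_voxels <- list()
    placed <- list()  # center (vox), radius (mm)
    truth <- NULL

    if (!is.null(specs) && nrow(specs) > 0) {
      assert_that(all(specs$organ %in% names(menu)),
                  paste("unknown organ(s):",
                        paste(setdiff(specs$organ, names(menu)), collapse = ", ")))
      for (i in seq_len(nrow(specs))) {
        organ <- specs$organ[i]
        volume_ml <- specs$volume_ml[i]
        suvmax <- specs$suvmax[i]
        if (organ == "liver")
          suvmax <- max(suvmax, 2.5 * config$liver$suv_mean)
        r_mm <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
        has_center <- all(c("cx", "cy", "cz") %in% names(specs)) &&
          !is.na(specs$cx[i])
        guard <- 2 * max(sp)
        found <- FALSE
        for (try in seq_len(200L)) {
          if (has_center) {
            ctr <- c(specs$cx[i], specs$cy[i], specs$cz[i])
          } else if (organ == "liver") {
            lo <- config$liver$center_frac * gd -
              (config$liver$size_mm / 2 - r_mm - max(sp)) / sp
            hi <- config$liver$center_frac * gd +
              (config$liver$size_mm / 2 - r_mm - max(sp)) / sp
            if (any(hi <= lo)) stop2(sprintf(
              "lesion %d (%.1f ml) does not fit inside the liver compartment", i, volume_ml))
            ctr <- stats::runif(3, lo, hi)
          } else {
            w <- ceiling(r_mm / sp) + 2
            ctr <- stats::runif(3, w + 1, gd - w - 1)
          }
          # keep clear of other lesions
          ok <- TRUE
          for (p in placed) {
            d <- sqrt(sum(((ctr - p$center) * sp)^2))
            if (d < r_mm + p$r_mm + guard) { ok <- FALSE; break }
          }
          # non-liver lesions must avoid both compartments
          if (ok && organ != "liver") {
            vox <- sphere_voxels(ctr, volume_ml, gd, sp)
            lin <- coord_to_linear(vox, gd)
            if (any(lin %in% bp_guard) || any(lin %in% lv_guard)) ok <- FALSE
          }
          if (ok) {
            vox <- sphere_voxels(ctr, volume_ml, gd, sp)
            found <- TRUE
            break
          }
          if (has_center) break
        }
        if (!found) stop2(sprintf("could not place lesion %d after bounded retries", i))
        lin <- coord_to_linear(vox, gd)
        vol[lin] <- suvmax
        id <- sprintf("F%03d", i)
        lesion_voxels[[id]] <- lin
        placed[[length(placed) + 1]] <- list(center = ctr, r_mm = r_mm)
        m <- menu[[organ]]
        truth <- rbind(truth, data.frame(
          focus_id = id,
          body_part = sample(m$body_part, 1),
          region = sample(m$region, 1),
          subregion = sample(m$subregion, 1),
          organ = organ,
          volume_ml = length(lin) * voxel_volume_ml(sp),
          volume_requested_ml = volume_ml,
          suvmax = suvmax,
          classification = specs$classification[i],
          cx = ctr[1], cy = ctr[2], cz = ctr[3],
          stringsAsFactors = FALSE))
      }
    }

    if (config$blur_fwhm_mm > 0)
      vol <- gaussian_blur(vol, sp, config$blur_fwhm_mm)

    all_lesion <- unlist(lesion_voxels, use.names = FALSE)
    bp_mask <- array(FALSE, gd); bp_mask[setdiff(bp_idx, all_lesion)] <- TRUE
    lv_mask <- array(FALSE, gd); lv_mask[setdiff(lv_idx, all_lesion)] <- TRUE
    label_map <- array(0L, gd)
    label_map[bp_mask] <- 1L
    label_map[lv_mask] <- 2L

    list(volume = suv_volume(vol, spacing = sp),
         bloodpool_mask = bp_mask, liver_mask = lv_mask,
         label_map = label_map,
         lesions = truth %||% data.frame(),
         lesion_voxels = lesion_voxels)
  })
}

#' Detector sensitivity profile
#'
#' Emulates an imperfect automated reader: the probability of flagging a
#' suspicious focus is a logistic function of log2 volume and SUVmax (so
#' sensitivity degrades for small, faint lesions); physiological foci are
#' falsely flagged at a constant rate; anatomical labels are corrupted at
#' per-level confusion rates.
#'
#' @param intercept,slope_log2_volume,slope_suvmax logistic coefficients of
#'   `P(flag suspicious) = plogis(intercept + slope_log2_volume * log2(MTV ml)
#'   + slope_suvmax * SUVmax)`. Slopes must be `>= 0` (sensitivity is
#'   monotone non-decreasing in volume and SUVmax).
#' @param fp_rate probability of flagging a physiological focus suspicious.
#' @param confusion named numeric: label corruption probability at
#'   `body_part`, `region`, `subregion`.
#' @return `detector_profile` list.
#' @export
detector_profile <- function(intercept = -1.9, slope_log2_volume = 1.0,
                             slope_suvmax = 0.35, fp_rate = 0.05,
                             confusion = c(body_part = 0.02, region = 0.12,
                                           subregion = 0.20)) {
  assert_that(slope_log2_volume >= 0 && slope_suvmax >= 0,
              "logistic slopes must be non-negative")
  assert_that(fp_rate >= 0 && fp_rate <= 1, "fp_rate must be in [0, 1]")
  assert_that(all(confusion >= 0 & confusion <= 1) &&
                all(c("body_part", "region", "subregion") %in% names(confusion)),
              "confusion must give probabilities in [0,1] for all three levels")
  structure(list(intercept = intercept,
                 slope_log2_volume = slope_log2_volume,
                 slope_suvmax = slope_suvmax, fp_rate = fp_rate,
                 confusion = confusion),
            class = "detector_profile")
}

#' @rdname detector_profile
#' @param profile a `detector_profile`.
#' @param volume_ml,suvmax focus size (ml) and maximum SUV.
#' @export
detector_sensitivity <- function(profile, volume_ml, suvmax) {
  stats::plogis(profile$intercept +
                  profile$slope_log2_volume * log2(volume_ml) +
                  profile$slope_suvmax * suvmax)
}

corrupt_labels <- function(labels, rate, vocab_level) {
  hit <- !is.na(labels) & stats::runif(length(labels)) < rate
  if (any(hit)) {
    labels[hit] <- vapply(labels[hit], function(l) {
      pool <- setdiff(vocab_level, l)
      if (length(pool) == 0) l else sample(pool, 1)
    }, character(1))
  }
  labels
}

#' Simulate a candidate (automated) read of a reference lesion table
#'
#' Each suspicious reference focus is flagged suspicious with the logistic
#' sensitivity of its volume and SUVmax; each physiological focus is flagged
#' at the false-positive rate; anatomical labels are corrupted at the
#' profile's per-level confusion rates. Deterministic for a fixed seed.
#'
#' @param truth reference lesion table (see [read_lesion_table()] columns).
#' @param profile a [detector_profile()].
#' @param seed RNG seed.
#' @param vocabulary label vocabulary for corruption draws.
#' @return Candidate lesion table with the same `(patient_id, focus_id)` keys
#'   and predicted `classification` and labels.
#' @export
simulate_detector <- function(truth, profile, seed = NULL,
                              vocabulary = pet_anatomy_vocabulary()) {
  assert_that(inherits(profile, "detector_profile"), "profile must be a detector_profile")
  with_seed(seed, {
    cand <- truth
    susp <- truth$classification == "suspicious"
    p_flag <- ifelse(susp,
                     detector_sensitivity(profile, truth$volume_ml, truth$suvmax),
                     profile$fp_rate)
    flagged <- stats::runif(nrow(truth)) < p_flag
    cand$classification <- ifelse(flagged, "suspicious", "unsuspicious")
    cand$body_part <- corrupt_labels(truth$body_part, profile$confusion["body_part"],
                                     vocabulary$body_part)
    cand$region <- corrupt_labels(truth$region, profile$confusion["region"],
                                  vocabulary$region)
    cand$subregion <- corrupt_labels(truth$subregion, profile$confusion["subregion"],
                                     vocabulary$subregion)
    cand
  })
}

#' Survival cohort configuration
#'
#' Per-organ metabolic tumor volume is drawn from a zero-inflated log-normal
#' law (organ-wise MTV distributions start at 0 ml: not every patient has
#' disease in every organ system); survival follows a proportional-hazards
#' model `h(t) = h0 * exp(sum_k beta_k * log2(MTV_k + 1))` with
#' administrative censoring at a fixed horizon.
#'
#' @param n_patients cohort size.
#' @param organs named list (organ system -> list(p_zero, meanlog, sdlog));
#'   log-normal parameters are on the natural-log ml scale.
#' @param beta named true log hazard ratios per doubling-scale covariate;
#'   names from the organ systems plus `"whole_body"`.
#' @param baseline_hazard events per month, > 0.
#' @param horizon_months administrative censoring horizon.
#' @param seed RNG seed.
#' @export
cohort_config <- function(n_patients = 50,
                          organs = list(
                            "bone" = list(p_zero = 0.40, meanlog = 2.2, sdlog = 1.2),
                            "lymph node" = list(p_zero = 0.25, meanlog = 2.3, sdlog = 1.1),
                            "liver" = list(p_zero = 0.55, meanlog = 2.2, sdlog = 1.2),
                            "lung" = list(p_zero = 0.60, meanlog = 1.2, sdlog = 1.0),
                            "soft tissue" = list(p_zero = 0.45, meanlog = 1.5, sdlog = 1.0)),
                          beta = c("whole_body" = 0.35),
                          baseline_hazard = 0.002,
                          horizon_months = 84,
                          seed = NULL) {
  assert_that(baseline_hazard > 0, "baseline hazard must be > 0")
  pz <- vapply(organs, function(o) o$p_zero, numeric(1))
  assert_that(all(pz >= 0 & pz <= 1), "zero-inflation probabilities must be in [0, 1]")
  assert_that(all(names(beta) %in% c(names(organs), "whole_body")),
              "beta names must be organ systems or 'whole_body'")
  structure(list(n_patients = as.integer(n_patients), organs = organs,
                 beta = beta, baseline_hazard = baseline_hazard,
                 horizon_months = horizon_months, seed = seed),
            class = "cohort_config")
}

organ_col <- function(x) gsub(" ", "_", x)

#' Generate a synthetic survival cohort
#'
#' Draws per-patient organ-wise MTV and event times from the configured
#' proportional-hazards model; censoring is administrative at the horizon.
#' The realized event fraction is attached to the result (an all-censored
#' cohort raises a warning, not an error).
#'
#' @param config a [cohort_config()] with its `seed` set.
#' @return List with `mtv` (patient x organ MTV table, ml, plus
#'   `whole_body`), `records` (survival table: `patient_id`, `time_months`,
#'   `event`, raw `mtv_*` and transformed `log2_mtv_*` covariates) and
#'   `event_fraction`.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  with_seed(config$seed %||% stop2("cohort_config$seed must be set"), {
    n <- config$n_patients
    organs <- names(config$organs)
    mtv <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (org in organs) {
      o <- config$organs[[org]]
      pos <- stats::runif(n) >= o$p_zero
      v <- numeric(n)
      v[pos] <- stats::rlnorm(sum(pos), o$meanlog, o$sdlog)
      mtv[[organ_col(org)]] <- v
    }
    mtv$whole_body <- rowSums(mtv[, organ_col(organs), drop = FALSE])

    lp <- numeric(n)
    for (nm in names(config$beta))
      lp <- lp + config$beta[[nm]] * log2p1(mtv[[organ_col(nm)]])
    rate <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n) / rate
    event <- as.integer(t_event <= config$horizon_months)
    time <- pmin(t_event, config$horizon_months)

    records <- data.frame(patient_id = mtv$patient_id,
                          time_months = time, event = event,
                          stringsAsFactors = FALSE)
    for (nm in c(organ_col(organs), "whole_body")) {
      records[[paste0("mtv_", nm)]] <- mtv[[nm]]
      records[[paste0("log2_mtv_", nm)]] <- log2p1(mtv[[nm]])
    }
    ev_frac <- mean(event)
    if (ev_frac == 0)
      warning("all survival times censored under this configuration")
    list(mtv = mtv, records = records, event_fraction = ev_frac)
  })
}
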