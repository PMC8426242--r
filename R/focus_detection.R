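# Reference-standard quantification: blood-pool detection threshold,
# connected-component focus extraction with a minimum-volume filter, SUVpeak,
# PERCIST measurability, and 50%-of-SUVmax MTV segmentation.

#' Summary statistics of a reference region
#'
#' Mean and population SD (divisor N) of the SUV over a masked region; the
#' blood-pool statistics drive the patient-specific detection threshold and
#' the liver statistics drive measurability.
#'
#' @param volume an [suv_volume()].
#' @param mask logical array on the same grid, or a vector of linear voxel
#'   indices; must be non-empty.
#' @param region region name (`"blood pool"` or `"liver"`).
#' @return `region_stats` list: `mean`, `sd`, `n_voxels`, `region`.
#' @export
region_stats <- function(volume, mask, region = "blood pool") {
  idx <- if (is.array(mask)) {
    assert_that(all(dim(mask) == dim(volume$data)),
                "mask grid does not match the volume grid")
    which(mask)
  } else as.integer(mask)
  assert_that(length(idx) >= 1, "region mask is empty")
  x <- volume$data[idx]
  m <- mean(x)
  structure(list(mean = m, sd = sqrt(mean((x - m)^2)),
                 n_voxels = length(idx), region = region),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("%s: mean SUV %.3f, SD %.3f (%d voxels)\n",
              x$region, x$mean, x$sd, x$n_voxels))
  invisible(x)
}

#' Patient-specific detection threshold
#'
#' `2 * mean + 2 * SD` of the mediastinal blood pool, the PERCIST-style
#' preselection threshold for FDG-avid foci.
#'
#' @param stats [region_stats()] of the blood pool.
#' @return SUV threshold.
#' @export
detection_threshold <- function(stats) {
  2 * stats$mean + 2 * stats$sd
}

#' PERCIST measurability threshold and flag
#'
#' A focus is measurable iff its SUVpeak strictly exceeds
#' `2 * mean + 2 * SD` of the liver.
#'
#' @param suvpeak the focus SUVpeak.
#' @param liver_stats [region_stats()] of the liver.
#' @return Logical flag.
#' @export
percist_measurable <- function(suvpeak, liver_stats) {
  suvpeak > 2 * liver_stats$mean + 2 * liver_stats$sd
}

# Connected components of a voxel index set, via a vectorized neighbour
# edge list + igraph. Returns a list of linear-index vectors.
components_from_indices <- function(idx, dims, connectivity = 26) {
  n <- length(idx)
  if (n == 0) return(list())
  off <- neighbor_offsets(connectivity)
  # half of the offsets suffices for an undirected edge list
  keep <- off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0)))
  off <- off[keep, , drop = FALSE]
  coord <- arrayInd(idx, dims)
  edges <- vector("list", nrow(off))
  for (m in seq_len(nrow(off))) {
    nb <- coord + matrix(off[m, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- coord_to_linear(nb[ok, , drop = FALSE], dims)
    j <- match(lin, idx)
    hit <- !is.na(j)
    edges[[m]] <- cbind(which(ok)[hit], j[hit])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(e) && nrow(e) > 0)
    g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership
  unname(split(idx, memb))
}

# Frontier BFS over the array: the connected component (given connectivity)
# of `seed` within {voxels : vol >= level}. Used for half-max region growth.
bfs_component <- function(vol, seed, level, connectivity = 26) {
  dims <- dim(vol)
  off <- neighbor_offsets(connectivity)
  visited <- array(FALSE, dims)
  if (vol[seed] < level) return(integer(0))
  visited[seed] <- TRUE
  frontier <- seed
  acc <- seed
  while (length(frontier) > 0) {
    coord <- arrayInd(frontier, dims)
    nxt <- integer(0)
    for (m in seq_len(nrow(off))) {
      nb <- coord + matrix(off[m, ], nrow(coord), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- coord_to_linear(nb[ok, , drop = FALSE], dims)
      lin <- unique(lin[!visited[lin] & vol[lin] >= level])
      if (length(lin) > 0) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
    acc <- c(acc, frontier)
  }
  sort(acc)
}

#' Extract FDG-avid foci above a detection threshold
#'
#' Connected components (default 26-neighbourhood) of the strictly
#' supra-threshold voxel set; components smaller than `min_volume_ml`
#' (default 0.5 ml, volume = voxel count x voxel volume) are neglected.
#'
#' @param volume an [suv_volume()].
#' @param threshold SUV detection threshold (> 0), typically
#'   [detection_threshold()] of the blood pool.
#' @param min_volume_ml minimum detection-mask volume retained.
#' @param connectivity 26 (default) or 6.
#' @return List of `pet_focus` objects: `focus_id`, `voxels` (linear
#'   indices), `volume_ml` (detection mask), `suvmax`, `max_voxel`. An empty
#'   list when nothing exceeds the threshold.
#' @export
detect_foci <- function(volume, threshold, min_volume_ml = 0.5, connectivity = 26) {
  assert_that(threshold > 0, "detection threshold must be > 0")
  vv <- voxel_volume_ml(volume$spacing)
  idx <- which(volume$data > threshold)
  comps <- components_from_indices(idx, dim(volume$data), connectivity)
  comps <- comps[vapply(comps, length, integer(1)) * vv >= min_volume_ml]
  # deterministic ordering: by first (smallest) linear index
  if (length(comps) > 1)
    comps <- comps[order(vapply(comps, min, numeric(1)))]
  lapply(seq_along(comps), function(i) {
    vox <- comps[[i]]
    vals <- volume$data[vox]
    structure(list(focus_id = sprintf("F%03d", i), voxels = vox,
                   volume_ml = length(vox) * vv,
                   suvmax = max(vals),
                   max_voxel = vox[which.max(vals)]),
              class = "pet_focus")
  })
}

#' SUVpeak of a focus
#'
#' Mean SUV over a 1.0-ml sphere (the PERCIST convention) positioned, with
#' its centre restricted to the focus voxels, so as to maximize that mean.
#' Sphere membership is decided by voxel-centre distance; for foci smaller
#' than the sphere, the sphere extends into the surroundings. Voxels falling
#' outside the grid are excluded from the mean.
#'
#' @param volume an [suv_volume()].
#' @param focus a `pet_focus` (or a vector of linear voxel indices).
#' @param sphere_ml sphere volume, default 1.0 ml.
#' @return SUVpeak (never above the focus SUVmax plus surrounding maxima).
#' @export
suv_peak <- function(volume, focus, sphere_ml = 1.0) {
  vox <- if (inherits(focus, "pet_focus")) focus$voxels else as.integer(focus)
  assert_that(length(vox) >= 1, "focus is empty")
  dims <- dim(volume$data)
  off <- sphere_offsets(volume$spacing, sphere_ml)
  centers <- arrayInd(vox, dims)
  n <- nrow(centers)
  sums <- numeric(n)
  cnts <- numeric(n)
  for (m in seq_len(nrow(off))) {
    nb <- centers + matrix(off[m, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- coord_to_linear(nb[ok, , drop = FALSE], dims)
    sums[ok] <- sums[ok] + volume$data[lin]
    cnts[ok] <- cnts[ok] + 1
  }
  max(sums / cnts)
}

#' Metabolic tumor volume at 50% of the local SUVmax
#'
#' Grows the MTV mask from the focus's maximum voxel through voxels with
#' `SUV >= 0.5 * SUVmax`, by connectivity, so adjacent structures above
#' half-maximum but not connected to this focus are excluded.
#'
#' @param volume an [suv_volume()].
#' @param focus a `pet_focus` with `suvmax > 0`.
#' @param connectivity 26 (default) or 6.
#' @return List with `mask` (linear voxel indices) and `mtv_ml`.
#' @export
segment_mtv <- function(volume, focus, connectivity = 26) {
  assert_that(inherits(focus, "pet_focus"), "focus must be a pet_focus")
  assert_that(focus$suvmax > 0, "focus SUVmax must be > 0")
  mask <- bfs_component(volume$data, focus$max_voxel, 0.5 * focus$suvmax,
                        connectivity)
  list(mask = mask, mtv_ml = length(mask) * voxel_volume_ml(volume$spacing))
}

#' Quantify every focus of an SUV volume
#'
#' End-to-end reference quantification: blood-pool threshold, focus
#' extraction with the 0.5-ml filter, SUVpeak, liver-based PERCIST
#' measurability, and 50%-SUVmax MTV per focus.
#'
#' @param volume an [suv_volume()].
#' @param bloodpool_mask,liver_mask logical arrays (or linear index vectors).
#' @param min_volume_ml,connectivity see [detect_foci()].
#' @return List with `foci` (list of `pet_focus`, each extended with
#'   `suvpeak`, `measurable`, `mtv_mask`, `mtv_ml`), `table` (per-focus
#'   `data.frame`), `bloodpool_stats`, `liver_stats`, `threshold`.
#' @export
quantify_volume <- function(volume, bloodpool_mask, liver_mask,
                            min_volume_ml = 0.5, connectivity = 26) {
  bp <- region_stats(volume, bloodpool_mask, "blood pool")
  lv <- region_stats(volume, liver_mask, "liver")
  thr <- detection_threshold(bp)
  foci <- detect_foci(volume, thr, min_volume_ml, connectivity)
  foci <- lapply(foci, function(f) {
    f$suvpeak <- suv_peak(volume, f)
    f$measurable <- percist_measurable(f$suvpeak, lv)
    seg <- segment_mtv(volume, f, connectivity)
    f$mtv_mask <- seg$mask
    f$mtv_ml <- seg$mtv_ml
    f
  })
  tab <- if (length(foci) == 0) data.frame() else data.frame(
    patient_id = volume$patient_id,
    focus_id = vapply(foci, `[[`, character(1), "focus_id"),
    volume_ml = vapply(foci, `[[`, numeric(1), "mtv_ml"),
    detection_volume_ml = vapply(foci, `[[`, numeric(1), "volume_ml"),
    suvmax = vapply(foci, `[[`, numeric(1), "suvmax"),
    suvpeak = vapply(foci, `[[`, numeric(1), "suvpeak"),
    measurable = vapply(foci, `[[`, logical(1), "measurable"),
    stringsAsFactors = FALSE)
  list(foci = foci, table = tab, bloodpool_stats = bp, liver_stats = lv,
       threshold = thr)
}

#' Aggregate MTV per patient
#'
#' Sums MTV over suspicious foci, whole-body or per organ system; patients
#' listed in `patients` but carrying no in-scope focus get 0 ml.
#'
#' @param lesion_table lesion table with `classification` present.
#' @param scope `"whole_body"` or `"per_organ"`.
#' @param measurable_only restrict to PERCIST-measurable foci first.
#' @param organ_map named map from region labels to organ systems; an
#'   unmapped region label raises an error naming it.
#' @param patients patient ids to report (default: those in the table).
#' @return `data.frame` with `patient_id` and `whole_body`, or one column
#'   per organ system.
#' @export
aggregate_mtv <- function(lesion_table, scope = c("whole_body", "per_organ"),
                          measurable_only = FALSE,
                          organ_map = default_organ_map(),
                          patients = NULL) {
  scope <- match.arg(scope)
  assert_that("classification" %in% names(lesion_table),
              "lesion table lacks classifications")
  patients <- patients %||% unique(lesion_table$patient_id)
  tab <- lesion_table[lesion_table$classification == "suspicious", , drop = FALSE]
  if (measurable_only && nrow(tab) > 0) {
    assert_that("measurable" %in% names(tab), "lesion table lacks measurability flags")
    tab <- tab[as.logical(tab$measurable), , drop = FALSE]
  }
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  if (scope == "whole_body") {
    s <- tapply(tab$volume_ml, tab$patient_id, sum)
    out$whole_body <- as.numeric(s[patients])
    out$whole_body[is.na(out$whole_body)] <- 0
    return(out)
  }
  bad <- setdiff(unique(tab$region), names(organ_map))
  assert_that(length(bad) == 0,
              paste("region label(s) missing from the organ map:",
                    paste(bad, collapse = ", ")))
  organs <- sort(unique(unname(organ_map)))
  tab$organ <- unname(organ_map[tab$region])
  for (org in organs) {
    sub <- tab[tab$organ == org, , drop = FALSE]
    s <- tapply(sub$volume_ml, sub$patient_id, sum)
    v <- as.numeric(s[patients])
    v[is.na(v)] <- 0
    out[[organ_col(org)]] <- v
  }
  out
}
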