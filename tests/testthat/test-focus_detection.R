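# helper: wrap an array as a volume on the standard PET grid
vol_of <- function(arr, spacing = c(3.18, 3.18, 5.0))
  suv_volume(arr, spacing = spacing)

# helper: build a pet_focus by hand from a voxel set
focus_of <- function(volume, vox) {
  vals <- volume$data[vox]
  structure(list(focus_id = "F001", voxels = vox,
                 volume_ml = length(vox) * prod(volume$spacing) / 1000,
                 suvmax = max(vals), max_voxel = vox[which.max(vals)]),
            class = "pet_focus")
}

test_that("region statistics use the population SD and reject empty masks", {
  arr <- array(1.5, dim = c(4, 4, 4))
  v <- vol_of(arr)
  rs <- region_stats(v, seq_len(64))
  expect_equal(rs$mean, 1.5)
  expect_equal(rs$sd, 0)
  arr2 <- array(0, dim = c(2, 2, 2))
  arr2[1] <- 1; arr2[2] <- 3
  rs2 <- region_stats(vol_of(arr2), c(1, 2))
  expect_equal(rs2$mean, 2)
  expect_equal(rs2$sd, 1)   # population SD, divisor N
  expect_error(region_stats(v, integer(0)), "empty")
})

test_that("phantom blood-pool statistics recover the generator's parameters", {
  cfg <- phantom_config(grid_dim = c(48, 48, 64), background_noise_sd = 0,
                        lesions = data.frame(), seed = 6)
  ph <- generate_phantom(cfg)
  rs <- region_stats(ph$volume, ph$bloodpool_mask)
  n <- rs$n_voxels
  expect_gt(n, 200)
  expect_lt(abs(rs$mean - 1.8), 3 * 0.2 / sqrt(n))
  expect_lt(abs(rs$sd - 0.2), 3 * 0.2 / sqrt(n))  # SE(sd) ~ sd/sqrt(2n)
})

test_that("detection and measurability thresholds follow 2*mean + 2*SD exactly", {
  mk <- function(mean, sd) structure(list(mean = mean, sd = sd, n_voxels = 10,
                                          region = "blood pool"),
                                     class = "region_stats")
  expect_equal(detection_threshold(mk(1.5, 0.25)), 3.5)
  expect_equal(detection_threshold(mk(2.0, 0.3)), 4.6)
  expect_equal(detection_threshold(mk(1.7, 0)), 3.4)
  liver <- mk(2.0, 0.3)
  expect_true(percist_measurable(5.0, liver))
  expect_false(percist_measurable(4.6, liver))   # strict inequality boundary
  expect_false(percist_measurable(1.0, liver))
})

test_that("detect_foci extracts a rendered lesion and drops sub-0.5-ml components", {
  les <- data.frame(volume_ml = 2.0, suvmax = 8, organ = "bone",
                    classification = "suspicious")
  cfg <- phantom_config(grid_dim = c(48, 48, 48), background_noise_sd = 0,
                        lesions = les, seed = 3)
  ph <- generate_phantom(cfg)
  foci <- detect_foci(ph$volume, 3.5)
  expect_length(foci, 1)
  expect_equal(foci[[1]]$suvmax, 8)
  expect_equal(foci[[1]]$volume_ml, ceiling(2 / 0.050562) * 0.050562)
  # a single supra-threshold voxel (0.0506 ml) is neglected
  arr <- array(1, dim = c(10, 10, 10))
  arr[5, 5, 5] <- 9
  expect_length(detect_foci(vol_of(arr), 3.5), 0)
  expect_length(detect_foci(vol_of(arr), 3.5, min_volume_ml = 0.05), 1)
  # nothing supra-threshold: empty list, not an error
  expect_length(detect_foci(vol_of(array(1, dim = c(6, 6, 6))), 3.5), 0)
})

test_that("separated lesions give two foci, abutting lesions one, matching flood fill", {
  arr <- array(0.5, dim = c(20, 20, 20))
  arr[3:5, 3:5, 3:5] <- 8          # block A
  arr[9:11, 3:5, 3:5] <- 8         # block B, separated by > 1 voxel
  v <- vol_of(arr)
  foci <- detect_foci(v, 4, min_volume_ml = 0)
  expect_length(foci, 2)
  oc <- canon_components(oracle_components(arr > 4, 26))
  expect_identical(canon_components(lapply(foci, `[[`, "voxels")), oc)
  arr[6:8, 3:5, 3:5] <- 8          # bridge: now abutting -> one focus
  expect_length(detect_foci(vol_of(arr), 4, min_volume_ml = 0), 1)
})

test_that("connected components match brute-force flood fill on random small grids", {
  for (s in 1:3) {
    set.seed(100 + s)
    dims <- sample(8:16, 3, replace = TRUE)
    mask <- array(stats::runif(prod(dims)) < 0.18, dim = dims)
    arr <- array(0, dim = dims)
    arr[mask] <- 9
    for (conn in c(6, 26)) {
      foci <- detect_foci(vol_of(arr), 1, min_volume_ml = 0, connectivity = conn)
      expect_identical(canon_components(lapply(foci, `[[`, "voxels")),
                       canon_components(oracle_components(mask, conn)),
                       info = sprintf("seed %d conn %d", s, conn))
    }
  }
})

test_that("SUVpeak equals the homogeneous value on large lesions and never exceeds SUVmax", {
  les <- data.frame(volume_ml = 20, suvmax = 8, organ = "bone",
                    classification = "suspicious")
  cfg <- phantom_config(grid_dim = c(48, 48, 48), background_noise_sd = 0,
                        lesions = les, seed = 9)
  ph <- generate_phantom(cfg)
  f <- detect_foci(ph$volume, 3.5)[[1]]
  expect_equal(suv_peak(ph$volume, f), 8)
  # fuzz: random blobs, mean over a sphere cannot exceed the maximum
  for (s in 1:5) {
    set.seed(200 + s)
    arr <- array(stats::runif(14^3, 0, 10), dim = c(14, 14, 14))
    v <- vol_of(arr)
    foci <- detect_foci(v, 8, min_volume_ml = 0)
    for (f in foci) expect_lte(suv_peak(v, f), f$suvmax)
  }
})

test_that("SUVpeak of a 3-voxel hot line matches the exhaustive centre search", {
  arr <- array(0.2, dim = c(15, 15, 9))
  arr[7, 7, 5] <- 8; arr[8, 7, 5] <- 6; arr[9, 7, 5] <- 4
  v <- vol_of(arr)
  vox <- which(arr > 0.2)
  expect_equal(suv_peak(v, vox),
               oracle_suvpeak(arr, v$spacing, vox), tolerance = 1e-12)
})

test_that("half-max segmentation keeps the core, drops sub-half rims, matches flood fill", {
  arr <- array(1, dim = c(20, 20, 20))
  core <- as.matrix(expand.grid(8:12, 8:12, 8:12))
  rim <- as.matrix(expand.grid(6:14, 6:14, 6:14))
  lin <- function(m) (m[, 3] - 1) * 400 + (m[, 2] - 1) * 20 + m[, 1]
  arr[lin(rim)] <- 3.9
  arr[lin(core)] <- 8
  v <- vol_of(arr)
  f <- focus_of(v, lin(core))
  seg <- segment_mtv(v, f)
  expect_setequal(seg$mask, lin(core))            # rim at 3.9 < 4 excluded
  expect_equal(seg$mtv_ml, 125 * prod(v$spacing) / 1000)
  # blurred sphere: equals brute-force flood fill from the seed at half-max
  les <- data.frame(volume_ml = 8, suvmax = 10, organ = "lung",
                    classification = "suspicious")
  cfg <- phantom_config(grid_dim = c(40, 40, 40), background_noise_sd = 0,
                        lesions = les, blur_fwhm_mm = 6, seed = 4)
  ph <- generate_phantom(cfg)
  vox <- ph$lesion_voxels[["F001"]]
  f2 <- focus_of(ph$volume, vox)
  seg2 <- segment_mtv(ph$volume, f2)
  mask_arr <- ph$volume$data >= 0.5 * f2$suvmax
  ocs <- oracle_components(mask_arr, 26)
  seed_comp <- ocs[[which(vapply(ocs, function(cp) f2$max_voxel %in% cp, logical(1)))]]
  expect_setequal(seg2$mask, seed_comp)
})

test_that("raising the detection threshold never increases focus count or detected volume", {
  cfg <- phantom_config(grid_dim = c(64, 64, 64), seed = 15)
  ph <- generate_phantom(cfg)
  thr <- c(3.0, 4.0, 5.0, 7.0)
  res <- lapply(thr, function(t) detect_foci(ph$volume, t, min_volume_ml = 0))
  counts <- vapply(res, length, integer(1))
  vols <- vapply(res, function(r) sum(vapply(r, `[[`, numeric(1), "volume_ml")),
                 numeric(1))
  expect_true(all(diff(vols) <= 1e-12))
  # focus count may transiently rise when one component splits, but the
  # supra-threshold voxel set itself is nested
  sets <- lapply(res, function(r) sort(unlist(lapply(r, `[[`, "voxels"))))
  for (i in seq_len(length(thr) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("MTV aggregation sums suspicious foci by scope and flags unmapped regions", {
  tab <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    focus_id = sprintf("F%d", 1:6),
    body_part = "thorax",
    region = c("bones", "lymph nodes", "lung", "bones", "breast", "liver"),
    subregion = NA_character_,
    volume_ml = c(2.0, 5.3, 1.1, 4.0, 2.5, 7.7),
    suvmax = 8, suvpeak = 7,
    measurable = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    classification = c("suspicious", "suspicious", "suspicious",
                       "suspicious", "unsuspicious", "suspicious"),
    stringsAsFactors = FALSE)
  wb <- aggregate_mtv(tab, "whole_body")
  expect_equal(wb$whole_body[wb$patient_id == "P1"], 7.3 + 1.1)
  expect_equal(wb$whole_body[wb$patient_id == "P2"], 4.0)
  po <- aggregate_mtv(tab, "per_organ")
  expect_equal(po$bone, c(2.0, 4.0, 0))
  expect_equal(po$lymph_node, c(5.3, 0, 0))
  expect_equal(po$lung, c(1.1, 0, 0))
  expect_equal(po$liver, c(0, 0, 7.7))
  expect_equal(po$soft_tissue, c(0, 0, 0))   # breast focus is unsuspicious
  # measurable-only drops the 1.1-ml lung focus
  wbm <- aggregate_mtv(tab, "whole_body", measurable_only = TRUE)
  expect_equal(wbm$whole_body[1], 7.3)
  # all-unsuspicious patient reports 0
  tab2 <- tab; tab2$classification <- "unsuspicious"
  expect_equal(aggregate_mtv(tab2, "whole_body")$whole_body, c(0, 0, 0))
  bad <- tab; bad$region[1] <- "spleen"
  expect_error(aggregate_mtv(bad, "per_organ",
                             organ_map = c("bones" = "bone")), "lymph nodes")
})
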