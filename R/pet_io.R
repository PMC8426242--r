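# I/O layer: SUV volumes (NIfTI-1), label masks, lesion tables and survival
# tables (CSV), metric reports (JSON).

#' Construct an SUV volume
#'
#' An SUV volume is a 3-D array of body-weight standardized uptake values with
#' anisotropic voxel spacing in mm. Axis order of the array matches the
#' spacing vector (x, y, z).
#'
#' @param data 3-D numeric array of SUV values (all `>= 0`).
#' @param spacing numeric length-3 voxel spacing in mm; default is the
#'   3.18 x 3.18 x 5.0 mm grid of a whole-body PET reconstruction.
#' @param patient_id character scalar identifying the patient.
#' @return An object of class `suv_volume` with fields `data`, `spacing`,
#'   `patient_id`.
#' @export
suv_volume <- function(data, spacing = c(3.18, 3.18, 5.0), patient_id = "P1") {
  assert_that(is.array(data) && length(dim(data)) == 3,
              sprintf("SUV volume must be a 3-D array, got %d dimension(s)",
                      length(dim(data))))
  assert_that(is.numeric(spacing) && length(spacing) == 3 && all(spacing > 0),
              "spacing must be three strictly positive values (mm)")
  n_neg <- sum(data < 0)
  assert_that(n_neg == 0,
              sprintf("SUV values must be non-negative; %d negative voxel(s) found", n_neg))
  structure(list(data = data, spacing = as.numeric(spacing),
                 patient_id = as.character(patient_id)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("SUV volume [%s]: %s voxels, spacing %s mm, voxel volume %.6f ml\n",
              x$patient_id, paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              voxel_volume_ml(x$spacing)))
  cat(sprintf("  SUV range: %.3f - %.3f\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Read an SUV volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the header (pixdim, mm); values are not
#' rescaled. Input must be 3-D and non-negative.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param patient_id patient identifier to attach (NIfTI has no such field).
#' @return An [suv_volume()].
#' @export
read_suv_volume <- function(path, patient_id = "P1") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  assert_that(length(d) == 3,
              sprintf("expected a 3-D SUV volume, got %d-D", length(d)))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  suv_volume(array(as.numeric(img), dim = d), spacing = spacing,
             patient_id = patient_id)
}

#' Write an SUV volume (or integer label mask) to NIfTI-1
#'
#' @param volume an [suv_volume()], or a 3-D array when `spacing` is given.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override for raw arrays.
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "suv_volume")) {
    arr <- volume$data
    spacing <- volume$spacing
  } else {
    arr <- volume
    assert_that(!is.null(spacing), "spacing required when writing a raw array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Anatomical label vocabulary
#'
#' Closed vocabulary of anatomical labels at three granularities (body part,
#' region, subregion), mirroring an expert whole-body FDG-PET read. A focus
#' always carries a body part and region; a subregion is optional.
#'
#' @return Named list with character vectors `body_part`, `region`,
#'   `subregion`.
#' @export
pet_anatomy_vocabulary <- function() {
  list(
    body_part = c("cranium", "neck", "thorax", "abdomen", "upper limb", "lower limb"),
    region = c("bones", "lymph nodes", "liver", "lung", "soft tissue",
               "breast", "pectoral muscle", "mediastinum", "spleen", "skin",
               "muscles", "pleura", "esophagus", "heart", "thymus"),
    subregion = c("spine", "scapula", "sternum", "ribs", "pelvis", "femur",
                  "axillary lymph nodes", "cervical lymph nodes",
                  "mesenterial lymph nodes", "lymph node station 1")
  )
}

#' Default mapping from region labels to organ systems
#'
#' Organ-wise MTV aggregation uses five organ systems: bone, lymph node,
#' liver, lung, soft tissue. Every region label of the vocabulary must map to
#' one of them.
#'
#' @return Named character vector (names = region labels, values = organ
#'   systems).
#' @export
default_organ_map <- function() {
  c("bones" = "bone", "lymph nodes" = "lymph node", "liver" = "liver",
    "lung" = "lung", "soft tissue" = "soft tissue", "breast" = "soft tissue",
    "pectoral muscle" = "soft tissue", "mediastinum" = "soft tissue",
    "spleen" = "soft tissue", "skin" = "soft tissue",
    "muscles" = "soft tissue", "pleura" = "lung", "esophagus" = "soft tissue",
    "heart" = "soft tissue", "thymus" = "soft tissue")
}

lesion_table_columns <- c("patient_id", "focus_id", "body_part", "region",
                          "subregion", "volume_ml", "suvmax", "suvpeak",
                          "measurable", "classification")

validate_lesion_table <- function(tab, vocabulary = pet_anatomy_vocabulary()) {
  required <- c("patient_id", "focus_id", "body_part", "region", "subregion",
                "volume_ml", "suvmax", "classification")
  missing_cols <- setdiff(required, names(tab))
  assert_that(length(missing_cols) == 0,
              paste("lesion table lacks column(s):",
                    paste(missing_cols, collapse = ", ")))
  key <- paste(tab$patient_id, tab$focus_id, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (patient_id, focus_id) key(s) in lesion table")
  bad_cls <- setdiff(unique(tab$classification), c("suspicious", "unsuspicious"))
  assert_that(length(bad_cls) == 0,
              paste("unknown classification value(s):", paste(bad_cls, collapse = ", ")))
  for (lvl in c("body_part", "region", "subregion")) {
    vals <- tab[[lvl]]
    vals <- vals[!is.na(vals)]
    bad <- setdiff(unique(vals), vocabulary[[lvl]])
    assert_that(length(bad) == 0,
                sprintf("unknown %s label(s): %s", lvl, paste(bad, collapse = ", ")))
  }
  invisible(tab)
}

#' Read / write a lesion table
#'
#' CSV (RFC 4180, header row) with columns `patient_id, focus_id, body_part,
#' region, subregion, volume_ml, suvmax, suvpeak, measurable, classification`.
#' A missing subregion is carried as `NA` (written as the explicit token `NA`,
#' never as an empty string) so that "absent" stays distinct from "wrong"
#' in the most-detailed-label logic. Anatomical labels are checked against
#' the configured vocabulary; `(patient_id, focus_id)` must be unique.
#'
#' @param path CSV path.
#' @param vocabulary label vocabulary, see [pet_anatomy_vocabulary()].
#' @return A `data.frame` lesion table.
#' @export
read_lesion_table <- function(path, vocabulary = pet_anatomy_vocabulary()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character",
                                        focus_id = "character",
                                        subregion = "character"),
                         na.strings = "NA")
  validate_lesion_table(tab, vocabulary)
  tab
}

#' @param table lesion table `data.frame`.
#' @rdname read_lesion_table
#' @export
write_lesion_table <- function(table, path, vocabulary = pet_anatomy_vocabulary()) {
  validate_lesion_table(table, vocabulary)
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a survival table
#'
#' CSV with `patient_id`, `time_months` (> 0), `event` (0/1) and one column
#' per covariate.
#'
#' @param path CSV path.
#' @return `data.frame` with one row per patient.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  validate_survival_table(tab)
  tab
}

#' @param table survival table `data.frame`.
#' @rdname read_survival_table
#' @export
write_survival_table <- function(table, path) {
  validate_survival_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

validate_survival_table <- function(tab) {
  for (col in c("patient_id", "time_months", "event")) {
    assert_that(col %in% names(tab), paste("survival table lacks column", col))
  }
  assert_that(all(tab$time_months > 0), "survival times must be > 0")
  assert_that(all(tab$event %in% c(0, 1)), "event must be 0 or 1")
  assert_that(!anyDuplicated(tab$patient_id), "duplicate patient_id in survival table")
  invisible(tab)
}

#' Write a metric report as JSON
#'
#' @param report a list (typically of metric objects) to serialize.
#' @param path output path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
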