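#' CT attenuation volumes and vertebral label masks
#'
#' `ct_volume()` wraps a 3-D attenuation array (Hounsfield units) with its
#' physical voxel spacing; `vertebra_mask()` wraps an integer label array of
#' identical dimensions with a label table mapping each label to a vertebral
#' level and subregion. The axis convention is fixed package-wide:
#' dimension 1 runs left-right, dimension 2 anterior-posterior (anterior at
#' low index), dimension 3 inferior-superior.
#'
#' @param data 3-D numeric array of attenuation values (HU).
#' @param spacing_mm Positive length-3 numeric, voxel spacing in mm per axis.
#' @param kvp Peak tube voltage of the acquisition (kVp). Calibration is only
#'   defined for 120-kVp protocols; other voltages are rejected at
#'   calibration time.
#' @param scanner_id Identifier matched against the calibration config.
#' @param contrast_phase One of `"none"`, `"arterial"`, `"portal_venous"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing_mm, kvp = 120, scanner_id = "synthetic",
                      contrast_phase = "none") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    qct_data_error("`spacing_mm` must be three positive finite values")
  }
  if (any(!is.finite(data))) {
    qct_data_error("attenuation volume contains non-finite values")
  }
  contrast_phase <- match.arg(contrast_phase,
                              c("none", "arterial", "portal_venous"))
  structure(
    list(data = data, spacing_mm = spacing_mm, kvp = kvp,
         scanner_id = scanner_id, contrast_phase = contrast_phase),
    class = "ct_volume"
  )
}

#' @rdname ct_volume
#' @param labels 3-D integer array; 0 is background.
#' @param label_map Data frame with columns `label`, `level`, `subregion`
#'   (`"body"`, `"posterior"`, or `NA` for an unpartitioned vertebra).
#' @export
vertebra_mask <- function(labels, label_map, spacing_mm) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  label_map <- as_tibble(label_map)
  stopifnot(all(c("label", "level", "subregion") %in% names(label_map)))
  if (any(labels < 0)) qct_data_error("mask labels must be non-negative")
  used <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(used %in% label_map$label)) {
    qct_data_error("mask contains labels absent from `label_map`")
  }
  body_per_level <- table(label_map$level[label_map$subregion %in% "body"])
  if (any(body_per_level > 1)) {
    qct_data_error("each level may have at most one body label")
  }
  structure(
    list(labels = labels, label_map = label_map,
         spacing_mm = as.numeric(spacing_mm)),
    class = "vertebra_mask"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 3), collapse = " x "),
      " mm, scanner ", x$scanner_id, ", ", x$kvp, " kVp, phase ",
      x$contrast_phase, "\n", sep = "")
  invisible(x)
}

#' @export
print.vertebra_mask <- function(x, ...) {
  cat("<vertebra_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, levels: ",
      paste(unique(x$label_map$level), collapse = ", "), "\n", sep = "")
  invisible(x)
}

voxel_volume_mm3 <- function(spacing_mm) prod(spacing_mm)

#' Read and write volume/mask scan pairs
#'
#' A "scan" on disk is a NIfTI attenuation volume (`<prefix>_vol.nii.gz`), a
#' NIfTI integer label mask (`<prefix>_mask.nii.gz`) and a plain-text label
#' table (`<prefix>_labels.csv` with columns `label`, `level`, `subregion`).
#' Voxel spacing travels in the NIfTI header.
#'
#' @param volume A [ct_volume()].
#' @param mask A [vertebra_mask()] on the same grid.
#' @param prefix Path prefix for the three files.
#' @return `write_scan()` returns `prefix` invisibly; `read_scan()` returns
#'   `list(volume =, mask =)`.
#' @export
write_scan <- function(volume, mask, prefix) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "vertebra_mask"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, paste0(prefix, "_vol.nii.gz"))
  msk <- RNifti::asNifti(array(as.integer(mask$labels), dim(mask$labels)))
  RNifti::pixdim(msk) <- mask$spacing_mm
  RNifti::writeNifti(msk, paste0(prefix, "_mask.nii.gz"))
  readr::write_csv(mask$label_map, paste0(prefix, "_labels.csv"),
                   progress = FALSE)
  invisible(prefix)
}

#' @rdname write_scan
#' @param kvp,scanner_id,contrast_phase Acquisition metadata to attach on
#'   read (NIfTI headers do not carry them).
#' @export
read_scan <- function(prefix, kvp = 120, scanner_id = "synthetic",
                      contrast_phase = "none") {
  vf <- paste0(prefix, "_vol.nii.gz")
  mf <- paste0(prefix, "_mask.nii.gz")
  lf <- paste0(prefix, "_labels.csv")
  for (f in c(vf, mf, lf)) {
    if (!file.exists(f)) qct_config_error(paste0("missing scan file: ", f))
  }
  img <- RNifti::readNifti(vf)
  spacing <- RNifti::pixdim(img)[1:3]
  msk <- RNifti::readNifti(mf)
  lm <- readr::read_csv(lf, show_col_types = FALSE, progress = FALSE)
  vol <- ct_volume(array(as.numeric(img), dim(img)[1:3]), spacing, kvp = kvp,
                   scanner_id = scanner_id, contrast_phase = contrast_phase)
  mask <- vertebra_mask(array(as.integer(msk), dim(msk)[1:3]), lm, spacing)
  list(volume = vol, mask = mask)
}
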