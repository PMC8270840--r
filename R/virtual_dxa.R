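#' Virtual posterior-anterior projection of calibrated bone
#'
#' Creates a DXA-equivalent areal density map by parallel projection of the
#' masked, calibrated volume along the anterior-posterior axis (grid axis 2).
#' Each projection-plane pixel receives the line integral of density through
#' the mask: `sum(density * dy)` with mg/cm^3 x mm -> g/cm^2 (factor 1e-4).
#' Only voxels inside the supplied body mask contribute, so lateral processes
#' are excluded by construction. Parallel projection conserves mass exactly:
#' the areal map integrated over pixel area equals the projected BMC.
#'
#' @param volume_bmd 3-D calibrated density array (mg/cm^3).
#' @param body_mask Logical 3-D array (union of the body masks to project).
#' @param spacing_mm Voxel spacing triple (mm).
#' @return An `areal_map`: list with `areal` (matrix, g/cm^2, left-right x
#'   inferior-superior), `footprint` (logical matrix, pixels receiving at
#'   least one mask voxel) and `pixel_spacing_mm`.
#' @export
project_pa <- function(volume_bmd, body_mask, spacing_mm) {
  stopifnot(all(dim(volume_bmd) == dim(body_mask)))
  contrib <- volume_bmd * body_mask
  areal <- apply(contrib, c(1, 3), sum) * spacing_mm[2] * 1e-4
  footprint <- apply(body_mask, c(1, 3), any)
  areal[!footprint] <- 0
  structure(
    list(areal = areal, footprint = footprint,
         pixel_spacing_mm = spacing_mm[c(1, 3)]),
    class = "areal_map"
  )
}

#' CT-based areal BMD from a projection map
#'
#' Mean areal density (g/cm^2) over the projection footprint. Patient-level
#' CT aBMD is computed per level and then averaged over the evaluable levels
#' (default L1-L4, the lumbar DXA window) by [ct_abmd_patient()].
#'
#' @param map An `areal_map` from [project_pa()].
#' @return Scalar g/cm^2, or `NA_real_` for an empty footprint.
#' @export
ct_abmd <- function(map) {
  stopifnot(inherits(map, "areal_map"))
  if (!any(map$footprint)) return(NA_real_)
  mean(map$areal[map$footprint])
}

#' @rdname ct_abmd
#' @param volume_bmd Calibrated density array (mg/cm^3).
#' @param mask A [vertebra_mask()].
#' @param levels Levels to project (default L1-L4).
#' @export
ct_abmd_patient <- function(volume_bmd, mask,
                            levels = vertebral_levels("L1", "L4")) {
  stopifnot(inherits(mask, "vertebra_mask"))
  present <- intersect(levels, unique(mask$label_map$level))
  vals <- vapply(present, function(lev) {
    body <- separate_body(mask, lev)
    ct_abmd(project_pa(volume_bmd, body, mask$spacing_mm))
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' T-scores and diagnostic classification for areal BMD
#'
#' `t_score()` standardizes an areal BMD against a young-adult reference
#' (`(abmd - mean) / sd`, in reference-SD units); `classify_tscore()` applies
#' the diagnostic bands: osteoporosis at T <= -2.5 (boundary inclusive), low
#' bone mass for -2.5 < T <= -1, normal above -1.
#'
#' @param abmd Areal BMD, g/cm^2 (vectorized).
#' @param ref A `t_score_reference()`.
#' @return `t_score()`: numeric T-scores; `classify_tscore()`: character
#'   classification.
#' @examples
#' ref <- t_score_reference(1.2, 0.12)
#' t_score(0.96, ref)
#' classify_tscore(t_score(0.96, ref))
#' @export
t_score <- function(abmd, ref) {
  stopifnot(inherits(ref, "t_score_reference"))
  (abmd - ref$mean) / ref$sd
}

#' @rdname t_score
#' @param mean,sd Young-adult reference mean and SD (g/cm^2, `sd > 0`).
#'   Defaults are configurable placeholders, not vendor reference data.
#' @export
t_score_reference <- function(mean = 1.18, sd = 0.12) {
  if (sd <= 0) qct_config_error("T-score reference SD must be positive")
  structure(list(mean = mean, sd = sd), class = "t_score_reference")
}

#' @rdname t_score
#' @param t T-score(s) in SD units.
#' @export
classify_tscore <- function(t) {
  ifelse(t <= -2.5, "osteoporosis",
         ifelse(t <= -1, "low bone mass", "normal"))
}
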