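#' Reduce a vertebra mask to its body compartment
#'
#' Returns the logical voxel mask of the vertebral body for one level. When
#' the mask carries explicit `body`/`posterior` subregion labels these are
#' passed through. For an unpartitioned vertebra (subregion `NA`) a geometric
#' heuristic is applied: the voxel-count profile along the anterior-posterior
#' axis is inspected and the vertebra is cut at the valley between the bulky
#' anterior body and the narrower posterior elements; the anterior side is
#' the body. The provenance is recorded in the `"body_source"` attribute
#' (`"labels"` or `"heuristic"`).
#'
#' @param mask A [vertebra_mask()].
#' @param level Vertebral level name present in the mask.
#' @return Logical 3-D array on the mask grid.
#' @export
separate_body <- function(mask, level) {
  stopifnot(inherits(mask, "vertebra_mask"))
  lm <- mask$label_map[mask$label_map$level == level, , drop = FALSE]
  if (nrow(lm) == 0) {
    qct_data_error(paste0("level ", level, " absent from mask"))
  }
  body_lab <- lm$label[lm$subregion %in% "body"]
  if (length(body_lab) == 1) {
    out <- array(mask$labels %in% lm$label & mask$labels == body_lab,
                 dim(mask$labels))
    attr(out, "body_source") <- "labels"
    return(out)
  }
  # unpartitioned vertebra: cut at the AP profile valley behind the body bulk
  vox <- array(mask$labels %in% lm$label, dim(mask$labels))
  profile <- apply(vox, 2, sum)
  support <- which(profile > 0)
  peak <- support[which.max(profile[support])]
  after <- support[support > peak]
  cut <- if (length(after) == 0) max(support) else {
    # deepest valley posterior to the peak
    after[which.min(profile[after])]
  }
  out <- vox
  out[, seq_len(dim(vox)[2]) > cut, ] <- FALSE
  attr(out, "body_source") <- "heuristic"
  out
}

#' Volumetric bone measures over a masked, calibrated volume
#'
#' `trabecular_vbmd()` and `integral_vbmd()` are arithmetic means of the
#' calibrated density (mg/cm^3) over the trabecular and body masks;
#' `bmc()` is the summed mineral mass in grams
#' (`sum(density) * voxel volume`, mg/cm^3 x mm^3 -> g). The identity
#' `bmc == integral_vbmd * body volume / 1000` holds to float tolerance.
#' An empty mask yields `NA` (non-evaluable), not an error.
#'
#' @param volume_bmd 3-D array of calibrated, contrast-corrected density
#'   (mg/cm^3), see [calibrate_volume()].
#' @param mask Logical 3-D array on the same grid.
#' @param spacing_mm Voxel spacing triple (mm), for `bmc()`.
#' @return Scalar measure, or `NA_real_` for an empty mask.
#' @export
trabecular_vbmd <- function(volume_bmd, mask) {
  if (!any(mask)) return(NA_real_)
  mean(volume_bmd[mask])
}

#' @rdname trabecular_vbmd
#' @export
integral_vbmd <- function(volume_bmd, mask) {
  if (!any(mask)) return(NA_real_)
  mean(volume_bmd[mask])
}

#' @rdname trabecular_vbmd
#' @export
bmc <- function(volume_bmd, mask, spacing_mm) {
  if (!any(mask)) return(NA_real_)
  # mg/cm^3 * mm^3 = 1e-6 g
  sum(volume_bmd[mask]) * voxel_volume_mm3(spacing_mm) * 1e-6
}

#' Per-level bone measures from a calibrated volume and mask
#'
#' For each requested level: reduce to the vertebral body
#' ([separate_body()]), erode metrically by `erosion_mm` to the trabecular
#' compartment ([erode_metric()]), and compute trabecular vBMD, integral
#' vBMD, BMC and body volume. Levels whose trabecular compartment erodes to
#' nothing are flagged `evaluable = FALSE` instead of failing.
#'
#' @param volume_bmd Calibrated density array (mg/cm^3).
#' @param mask A [vertebra_mask()] on the same grid.
#' @param levels Levels to measure; default all levels in the mask.
#' @param erosion_mm Cortical-exclusion erosion distance (mm); default 5, a
#'   physical distance independent of voxel spacing.
#' @param excluded Optional tibble `level`, `reason` (one of `"fracture"`,
#'   `"degeneration"`, `"other"`) marking levels excluded by quality review.
#' @return Tibble with one row per level: measures, `evaluable`, `excluded`,
#'   `exclusion_reason`.
#' @export
measure_levels <- function(volume_bmd, mask, levels = NULL, erosion_mm = 5,
                           excluded = NULL) {
  stopifnot(inherits(mask, "vertebra_mask"))
  stopifnot(all(dim(volume_bmd) == dim(mask$labels)))
  levels <- levels %||% unique(mask$label_map$level)
  sp <- mask$spacing_mm
  rows <- lapply(levels, function(lev) {
    body <- separate_body(mask, lev)
    trab <- crop_erode(body, erosion_mm, sp)
    vol_cm3 <- sum(body) * voxel_volume_mm3(sp) / 1000
    tibble(
      level = lev,
      trabecular_vbmd = trabecular_vbmd(volume_bmd, trab),
      integral_vbmd = integral_vbmd(volume_bmd, body),
      bmc = bmc(volume_bmd, body, sp),
      body_volume_cm3 = vol_cm3,
      n_trabecular_voxels = sum(trab),
      evaluable = any(trab)
    )
  })
  out <- bind_rows(rows)
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  if (!is.null(excluded) && nrow(excluded) > 0) {
    bad <- setdiff(excluded$reason, c("fracture", "degeneration", "other"))
    if (length(bad) > 0) {
      qct_data_error(paste0("unknown level-exclusion reasons: ",
                            paste(bad, collapse = ", ")))
    }
    i <- match(excluded$level, out$level)
    out$excluded[i[!is.na(i)]] <- TRUE
    out$exclusion_reason[i[!is.na(i)]] <- excluded$reason[!is.na(i)]
  }
  out
}

# erode inside the mask's bounding box only; the transform is local
crop_erode <- function(body, distance_mm, spacing_mm) {
  if (!any(body)) return(body)
  if (distance_mm == 0) return(body)
  idx <- which(body, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(body))
  sub <- body[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  er <- erode_metric(sub, distance_mm, spacing_mm)
  out <- array(FALSE, dim(body))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- er
  out
}

#' Measure one scan end to end
#'
#' Calibrates the volume ([calibrate_volume()]) and extracts per-level
#' measures ([measure_levels()]).
#'
#' @param volume A [ct_volume()].
#' @param mask A [vertebra_mask()] on the same grid.
#' @param config Calibration config ([read_calibration_config()]).
#' @inheritParams measure_levels
#' @return Tibble as in [measure_levels()].
#' @export
measure_scan <- function(volume, mask, config = default_calibration_config(),
                         levels = NULL, erosion_mm = 5, excluded = NULL) {
  bmd <- calibrate_volume(volume, config)
  measure_levels(bmd, mask, levels = levels, erosion_mm = erosion_mm,
                 excluded = excluded)
}

#' Aggregate per-level measures to the patient level
#'
#' Unweighted arithmetic mean of each measure over the evaluable,
#' non-excluded levels inside the eligibility window (default T12-L4, the
#' standard window for volumetric measures). A patient with no contributing
#' level is returned with `evaluable = FALSE` and `NA` measures.
#'
#' @param level_measures Tibble from [measure_levels()].
#' @param eligible_levels Levels eligible for aggregation.
#' @return One-row tibble: mean measures, `n_levels`, `evaluable`.
#' @examples
#' lm <- tibble::tibble(level = c("L1", "L2"),
#'   trabecular_vbmd = c(90, 110), integral_vbmd = c(150, 170),
#'   bmc = c(5, 6), body_volume_cm3 = c(30, 32),
#'   evaluable = TRUE, excluded = FALSE)
#' aggregate_patient(lm)
#' @export
aggregate_patient <- function(level_measures,
                              eligible_levels = vertebral_levels("T12", "L4")) {
  lm <- level_measures
  if (!"excluded" %in% names(lm)) lm$excluded <- FALSE
  use <- lm$evaluable & !lm$excluded & lm$level %in% eligible_levels
  vars <- intersect(c("trabecular_vbmd", "integral_vbmd", "bmc",
                      "body_volume_cm3"), names(lm))
  if (!any(use)) {
    out <- as_tibble(setNames(as.list(rep(NA_real_, length(vars))), vars))
    out$n_levels <- 0L
    out$evaluable <- FALSE
    return(out)
  }
  out <- as_tibble(lapply(setNames(vars, vars),
                          function(v) mean(lm[[v]][use])))
  out$n_levels <- sum(use)
  out$evaluable <- TRUE
  out
}
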