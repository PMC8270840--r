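#' Asynchronous HU-to-BMD calibration and contrast-phase correction
#'
#' In asynchronous quantitative CT, a density phantom scanned separately from
#' the patient yields a linear HU-to-BMD relation per (scanner, 120 kVp)
#' protocol: `bmd = slope * hu + intercept` in mg/cm^3. Intravenous contrast
#' medium inflates attenuation, so scans acquired in an enhanced phase get a
#' second linear map applied to the calibrated density. Both steps are applied
#' to the whole volume, in that order, before any bone measure is extracted.
#'
#' Shipped example coefficients are synthetic placeholders: real conversion
#' equations are scanner-specific and must be supplied via
#' [read_calibration_config()].
#'
#' @param scanner_id Scanner/protocol identifier.
#' @param slope Calibration slope (mg/cm^3 per HU); must be positive.
#' @param intercept Calibration intercept (mg/cm^3).
#' @return `calibration_model()` / `contrast_correction()` return small
#'   classed records; the conversion functions return numeric vectors/arrays
#'   shaped like their input.
#' @export
calibration_model <- function(scanner_id, slope, intercept) {
  if (!is.numeric(slope) || slope <= 0) {
    qct_config_error("calibration slope must be positive")
  }
  structure(list(scanner_id = scanner_id, slope = slope,
                 intercept = intercept),
            class = "calibration_model")
}

#' @rdname calibration_model
#' @param phase `"arterial"` or `"portal_venous"`.
#' @export
contrast_correction <- function(phase, slope, intercept) {
  phase <- match.arg(phase, c("arterial", "portal_venous"))
  if (!is.numeric(slope) || slope <= 0) {
    qct_config_error("contrast-correction slope must be positive")
  }
  structure(list(phase = phase, slope = slope, intercept = intercept),
            class = "contrast_correction")
}

#' @rdname calibration_model
#' @param hu Attenuation in HU (scalar, vector or array).
#' @param model A [calibration_model()].
#' @export
hu_to_bmd <- function(hu, model) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * hu + model$intercept
}

#' @rdname calibration_model
#' @param bmd Calibrated density in mg/cm^3 (scalar, vector or array).
#' @param corrections Named list of [contrast_correction()] objects (names =
#'   phases), as produced by [read_calibration_config()].
#' @export
correct_contrast <- function(bmd, phase, corrections) {
  phase <- match.arg(phase, c("none", "arterial", "portal_venous"))
  if (phase == "none") return(bmd)
  corr <- corrections[[phase]]
  if (is.null(corr)) {
    qct_config_error(paste0("no contrast correction configured for phase '",
                            phase, "'"))
  }
  corr$slope * bmd + corr$intercept
}

# inverse maps, used by the phantom generator to synthesize attenuation so
# that calibration + correction recover ground truth exactly
bmd_to_hu <- function(bmd, model) (bmd - model$intercept) / model$slope
uncorrect_contrast <- function(bmd, phase, corrections) {
  if (phase == "none") return(bmd)
  corr <- corrections[[phase]]
  if (is.null(corr)) {
    qct_config_error(paste0("no contrast correction configured for phase '",
                            phase, "'"))
  }
  (bmd - corr$intercept) / corr$slope
}

#' Calibration configuration files
#'
#' A calibration config (YAML or JSON) lists per-scanner HU-to-BMD
#' coefficients and per-phase contrast corrections:
#' ```yaml
#' scanners:
#'   - {scanner_id: scannerA, slope: 0.85, intercept: -3.2}
#' contrast:
#'   - {phase: portal_venous, slope: 0.9, intercept: -5}
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list with elements `scanners` (named list of
#'   [calibration_model()]) and `contrast` (named list of
#'   [contrast_correction()]).
#' @export
read_calibration_config <- function(path) {
  if (!file.exists(path)) {
    qct_config_error(paste0("calibration config not found: ", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scanners <- lapply(raw$scanners, function(s) {
    calibration_model(s$scanner_id, s$slope, s$intercept)
  })
  names(scanners) <- vapply(scanners, `[[`, "", "scanner_id")
  contrast <- lapply(raw$contrast %||% list(), function(s) {
    contrast_correction(s$phase, s$slope, s$intercept)
  })
  names(contrast) <- vapply(contrast, `[[`, "", "phase")
  list(scanners = scanners, contrast = contrast)
}

#' @rdname read_calibration_config
#' @param config Config list as returned by `read_calibration_config()`.
#' @export
write_calibration_config <- function(config, path) {
  out <- list(
    scanners = lapply(unname(config$scanners), unclass),
    contrast = lapply(unname(config$contrast), unclass)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Calibrate a CT volume to volumetric BMD
#'
#' Looks up the volume's scanner in the config, converts HU to mg/cm^3, and
#' applies the contrast correction for the volume's acquisition phase. Tube
#' voltages other than 120 kVp are rejected: asynchronous calibration is
#' voltage-specific and only 120-kVp relations are modelled.
#'
#' @param volume A [ct_volume()].
#' @param config Calibration config, see [read_calibration_config()].
#' @return A numeric 3-D array of volumetric BMD (mg/cm^3) on the volume's
#'   grid. Negative values are possible (air, fat) and are masked out by the
#'   bone measures downstream.
#' @export
calibrate_volume <- function(volume, config) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!isTRUE(all.equal(volume$kvp, 120))) {
    qct_data_error(paste0("unsupported tube voltage: ", volume$kvp,
                          " kVp (calibration defined for 120 kVp only)"))
  }
  model <- config$scanners[[volume$scanner_id]]
  if (is.null(model)) {
    qct_config_error(paste0("no calibration for scanner '",
                            volume$scanner_id, "'"))
  }
  bmd <- hu_to_bmd(volume$data, model)
  correct_contrast(bmd, volume$contrast_phase, config$contrast)
}

# identity calibration + synthetic contrast corrections; used as phantom
# defaults and in examples
default_calibration_config <- function() {
  list(
    scanners = list(
      synthetic = calibration_model("synthetic", 1, 0)
    ),
    contrast = list(
      arterial = contrast_correction("arterial", 0.88, -6),
      portal_venous = contrast_correction("portal_venous", 0.92, -9)
    )
  )
}
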