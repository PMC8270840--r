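#' Specify a digital vertebral phantom
#'
#' A phantom is a stack of vertebra-like objects on a soft-tissue background:
#' each level has a vertebral body with a rounded (superellipse) axial
#' cross-section, a cortical shell of known thickness around a trabecular
#' core, and a posterior-elements block behind the body. Densities are ground
#' truth in mg/cm^3; attenuation is synthesized by inverting the calibration
#' (and, for enhanced phases, the contrast correction), so the calibration
#' chain recovers ground truth exactly in the noiseless case. An anterior
#' wedge deformity (fractional height loss) can be imposed per level to
#' emulate Genant-gradable fractures.
#'
#' @param levels Character vector of vertebral levels (subset of T1..L5).
#' @param body_extent_mm Length-3 box extents of each vertebral body
#'   (left-right, anterior-posterior, inferior-superior), mm.
#' @param shell_thickness_mm Cortical shell thickness, mm (> 0).
#' @param trabecular_density,cortical_density,posterior_density,background_density
#'   Ground-truth densities, mg/cm^3.
#' @param noise_sd Gaussian attenuation noise SD, HU.
#' @param spacing_mm Voxel spacing triple, mm.
#' @param contrast_phase `"none"`, `"arterial"` or `"portal_venous"`.
#' @param fracture_height_loss Fractional anterior height reduction in
#'   `[0, 1)`; scalar (all levels) or named per level.
#' @param seed Integer RNG seed; regeneration with the same spec is
#'   bit-identical.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(levels = c("T12", "L1", "L2", "L3", "L4"),
                         body_extent_mm = c(34, 28, 26),
                         shell_thickness_mm = 3,
                         trabecular_density = 100,
                         cortical_density = 400,
                         posterior_density = 300,
                         background_density = 30,
                         noise_sd = 10,
                         spacing_mm = c(1, 1, 1),
                         contrast_phase = "none",
                         fracture_height_loss = 0,
                         seed = 1L) {
  all_levels <- vertebral_levels("T1", "L5")
  if (length(levels) == 0 || !all(levels %in% all_levels)) {
    qct_data_error("`levels` must be a non-empty subset of T1..L5")
  }
  if (shell_thickness_mm <= 0) qct_data_error("shell thickness must be > 0")
  dens <- c(trabecular_density, cortical_density, posterior_density,
            background_density)
  if (any(dens < 0)) qct_data_error("densities must be non-negative")
  if (noise_sd < 0) qct_data_error("noise_sd must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    qct_data_error("spacing components must be positive")
  }
  hl <- fracture_height_loss
  if (is.null(names(hl))) {
    hl <- setNames(rep(hl[1], length(levels)), levels)
  } else {
    full <- setNames(rep(0, length(levels)), levels)
    full[names(hl)] <- hl
    hl <- full
  }
  if (any(hl < 0 | hl >= 1)) {
    qct_data_error("fracture_height_loss must lie in [0, 1)")
  }
  contrast_phase <- match.arg(contrast_phase,
                              c("none", "arterial", "portal_venous"))
  structure(
    list(levels = levels, body_extent_mm = as.numeric(body_extent_mm),
         shell_thickness_mm = shell_thickness_mm,
         trabecular_density = trabecular_density,
         cortical_density = cortical_density,
         posterior_density = posterior_density,
         background_density = background_density,
         noise_sd = noise_sd, spacing_mm = spacing_mm,
         contrast_phase = contrast_phase, fracture_height_loss = hl,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a seeded digital phantom
#'
#' Renders the phantom described by a [phantom_spec()]: a [ct_volume()] of
#' attenuation (HU), a [vertebra_mask()] with one body label and one
#' posterior-elements label per level, and a ground-truth table with exact
#' per-level densities, volumes, BMC and Genant grade. The trabecular core is
#' defined metrically: body voxels deeper than `shell_thickness_mm` from the
#' body surface (same distance transform as the measurement erosion), so any
#' erosion distance exceeding the shell thickness lands strictly inside the
#' core.
#'
#' @param spec A [phantom_spec()].
#' @param calibration [calibration_model()] inverted when synthesizing HU.
#' @param corrections Named list of [contrast_correction()]s, inverted when
#'   `spec$contrast_phase` is an enhanced phase.
#' @return `list(volume, mask, truth, spec)` of class `qct_phantom`; `truth`
#'   is a tibble with one row per level.
#' @examples
#' ph <- generate_phantom(phantom_spec(levels = "L1", noise_sd = 0))
#' ph$truth
#' @export
generate_phantom <- function(spec,
                             calibration = calibration_model("synthetic", 1, 0),
                             corrections = default_calibration_config()$contrast) {
  stopifnot(inherits(spec, "phantom_spec"))
  ex <- spec$body_extent_mm
  sp <- spec$spacing_mm
  if (any(ex <= sp)) {
    abort("body extent must exceed voxel spacing in every direction",
          class = "qct_geometry_error")
  }
  if (any(ex <= 2 * spec$shell_thickness_mm)) {
    abort("body extent must exceed twice the shell thickness",
          class = "qct_geometry_error")
  }

  margin <- 4                      # soft-tissue rim, mm
  pdepth <- 0.5 * ex[2]            # posterior-elements depth, mm
  gap <- 6                         # intervertebral gap, mm
  nl <- length(spec$levels)
  nx <- ceiling((ex[1] + 2 * margin) / sp[1])
  ny <- ceiling((ex[2] + pdepth + 2 * margin) / sp[2])
  nz <- ceiling((nl * (ex[3] + gap) + gap) / sp[3])

  xc <- (seq_len(nx) - 0.5) * sp[1]
  yc <- (seq_len(ny) - 0.5) * sp[2]
  zc <- (seq_len(nz) - 0.5) * sp[3]
  cx <- margin + ex[1] / 2
  ymin <- margin
  cy <- ymin + ex[2] / 2

  # superellipse (exponent 4) axial cross-section of the body
  u <- abs(2 * (xc - cx) / ex[1])
  v <- abs(2 * (yc - cy) / ex[2])
  inside_xy <- outer(u^4, v^4, `+`) <= 1
  yfrac <- pmin(pmax((yc - ymin) / ex[2], 0), 1)

  labels <- array(0L, c(nx, ny, nz))
  density <- array(spec$background_density, c(nx, ny, nz))
  truth <- vector("list", nl)
  maps <- vector("list", nl)
  voxvol <- voxel_volume_mm3(sp)

  for (l in seq_len(nl)) {
    lev <- spec$levels[l]
    r <- spec$fracture_height_loss[[lev]]
    cz <- gap + (l - 1) * (ex[3] + gap) + ex[3] / 2
    halfh <- (ex[3] / 2) * (1 - r * (1 - yfrac))   # anterior wedge
    zin <- abs(outer(rep(1, ny), zc) - cz) <=
      outer(halfh, rep(1, nz))                     # ny x nz
    kidx <- which(colSums(zin) > 0)
    if (length(kidx) == 0) {
      abort("degenerate geometry: body has no voxels along the axial axis",
            class = "qct_geometry_error")
    }
    nzs <- length(kidx)
    body <- array(inside_xy, c(nx, ny, nzs)) &
      array(rep(zin[, kidx, drop = FALSE], each = nx), c(nx, ny, nzs))
    if (!any(body)) {
      abort("degenerate geometry: empty vertebral body",
            class = "qct_geometry_error")
    }

    # cortical shell = body voxels within shell_thickness of the surface
    core <- erode_metric(body, spec$shell_thickness_mm, sp)

    # posterior elements: narrower block behind the body, disjoint from it
    post <- array(FALSE, c(nx, ny, nzs))
    px <- abs(xc - cx) <= 0.25 * ex[1]
    py <- yc > ymin + ex[2] & yc <= ymin + ex[2] + pdepth
    pz <- abs(zc[kidx] - cz) <= 0.3 * ex[3]
    post[px, py, pz] <- TRUE
    post <- post & !body

    blab <- 2L * l - 1L
    plab <- 2L * l
    sub <- labels[, , kidx]
    sub[body] <- blab
    sub[post] <- plab
    labels[, , kidx] <- sub
    dsub <- density[, , kidx]
    dsub[body] <- spec$cortical_density
    dsub[core] <- spec$trabecular_density
    dsub[post] <- spec$posterior_density
    density[, , kidx] <- dsub

    n_body <- sum(body)
    n_core <- sum(core)
    integral <- (n_core * spec$trabecular_density +
                 (n_body - n_core) * spec$cortical_density) / n_body
    vol_cm3 <- n_body * voxvol / 1000
    truth[[l]] <- tibble(
      level = lev,
      trabecular_vbmd = spec$trabecular_density,
      integral_vbmd = integral,
      body_volume_cm3 = vol_cm3,
      bmc_g = integral * vol_cm3 / 1000,
      reference_height_mm = ex[3],
      anterior_height_mm = ex[3] * (1 - r),
      genant_grade = genant_grade(ex[3] * (1 - r), ex[3])
    )
    maps[[l]] <- tibble(label = c(blab, plab), level = lev,
                        subregion = c("body", "posterior"))
  }

  observed <- uncorrect_contrast(density, spec$contrast_phase, corrections)
  hu <- bmd_to_hu(observed, calibration)
  if (spec$noise_sd > 0) {
    hu <- withr::with_seed(
      spec$seed,
      hu + array(rnorm(length(hu), 0, spec$noise_sd), dim(hu))
    )
  }

  structure(
    list(
      volume = ct_volume(hu, sp, kvp = 120,
                         scanner_id = calibration$scanner_id,
                         contrast_phase = spec$contrast_phase),
      mask = vertebra_mask(labels, bind_rows(maps), sp),
      truth = bind_rows(truth),
      spec = spec
    ),
    class = "qct_phantom"
  )
}

#' Semiquantitative vertebral fracture grade from height loss
#'
#' Grades a vertebra by its fractional anterior height reduction
#' `r = 1 - anterior/reference` using the conventional semiquantitative
#' bands: grade 0 below 20% reduction, grade 1 for 20-25%, grade 2 for
#' 25-40%, grade 3 above 40%. Fracture status dichotomizes as grade >= 1.
#'
#' @param anterior_height,reference_height Heights in mm (> 0); vectorized.
#' @return Integer grade(s) in 0..3.
#' @examples
#' genant_grade(c(30, 22.5, 15), 30)
#' @export
genant_grade <- function(anterior_height, reference_height) {
  if (any(anterior_height <= 0) || any(reference_height <= 0)) {
    qct_data_error("vertebral heights must be positive")
  }
  r <- 1 - anterior_height / reference_height
  ifelse(r < 0.20, 0L, ifelse(r < 0.25, 1L, ifelse(r <= 0.40, 2L, 3L)))
}
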