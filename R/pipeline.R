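#' Simulate a scan set on disk
#'
#' Writes a self-contained synthetic study to `dir`: one phantom scan per
#' patient (volume + mask + label table, see [write_scan()]), a
#' `manifest.csv` listing the scans with acquisition metadata, a
#' `cohort.csv` with demographics, DXA measures and fracture status, and a
#' `calibration.yaml`. Fractured patients receive lower trabecular density
#' and a wedge deformity at one level; fracture status in the cohort table
#' is the Genant dichotomization (grade >= 1) of the imposed height loss.
#'
#' @param dir Output directory (created if needed).
#' @param n_patients Number of patients.
#' @param seed Integer seed; the whole set is deterministic given the seed.
#' @param levels Vertebral levels per phantom.
#' @param spacing_mm Voxel spacing of the phantoms.
#' @param noise_sd Attenuation noise SD (HU).
#' @return The manifest tibble, invisibly.
#' @export
simulate_scan_set <- function(dir, n_patients = 20, seed = 1L,
                              levels = c("L1", "L2", "L3"),
                              spacing_mm = c(1.5, 1.5, 1.5),
                              noise_sd = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- default_calibration_config()
  write_calibration_config(config, file.path(dir, "calibration.yaml"))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_patients), function(i) {
      fractured <- i > n_patients / 2
      trab <- max(if (fractured) rnorm(1, 62.8, 27.5) else
        rnorm(1, 113.5, 34.3), 15)
      loss <- setNames(rep(0, length(levels)), levels)
      if (fractured) loss[sample(levels, 1)] <- stats::runif(1, 0.25, 0.5)
      spec <- phantom_spec(
        levels = levels, body_extent_mm = c(26, 22, 20),
        shell_thickness_mm = 3, trabecular_density = trab,
        cortical_density = trab + 250, posterior_density = trab + 180,
        noise_sd = noise_sd, spacing_mm = spacing_mm,
        fracture_height_loss = loss,
        seed = seed + i
      )
      ph <- generate_phantom(spec, calibration = config$scanners$synthetic,
                             corrections = config$contrast)
      prefix <- file.path(dir, sprintf("pat%03d", i))
      write_scan(ph$volume, ph$mask, prefix)
      grade <- max(ph$truth$genant_grade)
      tibble(
        patient_id = i, prefix = sprintf("pat%03d", i),
        scanner_id = "synthetic", contrast_phase = "none", kvp = 120,
        fracture = grade >= 1,
        age = round(if (fractured) rnorm(1, 72, 9.3) else rnorm(1, 64.3, 8.6), 1),
        sex = ifelse(rbinom(1, 1, 0.73) == 1, "F", "M"),
        dxa_abmd = round(if (fractured) rnorm(1, 0.948, 0.204) else
          rnorm(1, 1.076, 0.219), 3),
        manual_vbmd = round(trab * rnorm(1, 1, 0.04), 1)
      )
    })
    manifest <- bind_rows(rows)
    readr::write_csv(
      manifest[c("patient_id", "prefix", "scanner_id", "contrast_phase", "kvp")],
      file.path(dir, "manifest.csv"), progress = FALSE)
    cohort <- manifest[c("patient_id", "age", "sex", "fracture",
                         "dxa_abmd", "manual_vbmd")]
    cohort$dxa_tscore <- round(t_score(cohort$dxa_abmd, t_score_reference()), 2)
    readr::write_csv(cohort, file.path(dir, "cohort.csv"), progress = FALSE)
    invisible(manifest)
  })
}

#' Fracture-association statistics for a cohort table
#'
#' Runs the full statistics stage on an assembled cohort: group comparison
#' of characteristics, crude and covariate-adjusted standardized odds
#' ratios, per-measure ROC/AUC, and paired DeLong comparisons of every
#' CT-based measure against DXA aBMD (when present). All bone measures are
#' risk-oriented (lower = higher fracture odds).
#'
#' @param cohort Tibble with a logical `fracture` column and measure
#'   columns.
#' @param measures Measure columns to analyze; defaults to the standard set
#'   intersected with the available columns.
#' @param adjust Covariates for the adjusted OR models.
#' @return Named list of tibbles: `group_table`, `or_table`, `auc_table`,
#'   `delong_table`.
#' @export
run_stats <- function(cohort,
                      measures = c("dxa_tscore", "dxa_abmd", "ct_abmd",
                                   "bmc", "integral_vbmd",
                                   "trabecular_vbmd", "manual_vbmd"),
                      adjust = c("age", "sex")) {
  measures <- intersect(measures, names(cohort))
  adjust <- intersect(adjust, names(cohort))
  if (!length(measures)) qct_data_error("no measure columns found")

  group_table <- group_compare(
    cohort, .data$fracture,
    vars = intersect(c("age", measures), names(cohort))
  )

  or_one <- function(m, adj) {
    fit <- fracture_or(cohort, .data$fracture, !!rlang::sym(m),
                       adjust = if (length(adj)) adj else NULL)
    mutate(glance(fit), measure = m, .before = 1)
  }
  or_table <- bind_rows(
    lapply(measures, or_one, adj = character(0)),
    lapply(measures, or_one, adj = adjust)
  )

  auc_table <- bind_rows(lapply(measures, function(m) {
    r <- roc_curve(cohort, .data$fracture, !!rlang::sym(m))
    mutate(glance(r), measure = m, .before = 1)
  }))

  delong_table <- NULL
  if ("dxa_abmd" %in% measures) {
    others <- setdiff(measures, "dxa_abmd")
    delong_table <- bind_rows(lapply(others, function(m) {
      dl <- delong_test(cohort, .data$fracture, !!rlang::sym(m), .data$dxa_abmd)
      mutate(glance(dl), measure = m, versus = "dxa_abmd", .before = 1)
    }))
  }

  list(group_table = group_table, or_table = or_table,
       auc_table = auc_table, delong_table = delong_table)
}

#' Run the full opportunistic-screening pipeline
#'
#' Orchestrates the analysis end to end: validates the configuration (fail
#' fast, before any computation), reads the calibration config, extracts
#' per-level and per-patient bone measures from every scan in the manifest,
#' assembles the cohort, applies the exclusion cascade if the cohort table
#' carries exclusion flags, runs the statistics stage, transfers the
#' trabecular-vBMD diagnostic cutoffs to integral vBMD, and writes all
#' results (CSV/JSON plus a run log with package version and config hash)
#' to the output directory. The run is deterministic given the config.
#'
#' @param config Named list or path to a YAML file with fields `input_dir`
#'   (containing `manifest.csv`, `cohort.csv` and the scan files),
#'   `calibration` (path to the calibration config), `output_dir`, and
#'   optional `erosion_mm` (default 5), `volumetric_levels` (default
#'   T12-L4), `areal_levels` (default L1-L4), `adjust` (default age, sex),
#'   `seed`.
#' @return Named list with `cohort`, `measures`, `stats`, `thresholds`,
#'   `audit`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      qct_config_error(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  for (f in c("input_dir", "calibration", "output_dir")) {
    if (is.null(config[[f]])) {
      qct_config_error(paste0("config field missing: ", f))
    }
  }
  manifest_path <- file.path(config$input_dir, "manifest.csv")
  cohort_path <- file.path(config$input_dir, "cohort.csv")
  for (p in c(config$calibration, manifest_path, cohort_path)) {
    if (!file.exists(p)) qct_config_error(paste0("input not found: ", p))
  }
  erosion_mm <- config$erosion_mm %||% 5
  vol_levels <- config$volumetric_levels %||% vertebral_levels("T12", "L4")
  areal_levels <- config$areal_levels %||% vertebral_levels("L1", "L4")
  adjust <- config$adjust %||% c("age", "sex")

  calib <- read_calibration_config(config$calibration)
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  cohort_in <- readr::read_csv(cohort_path, show_col_types = FALSE,
                               progress = FALSE)

  per_level <- vector("list", nrow(manifest))
  per_patient <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    scan <- withCallingHandlers(
      read_scan(file.path(config$input_dir, row$prefix),
                kvp = row$kvp %||% 120,
                scanner_id = row$scanner_id %||% "synthetic",
                contrast_phase = row$contrast_phase %||% "none"),
      error = function(e) e
    )
    bmd <- calibrate_volume(scan$volume, calib)
    lm <- measure_levels(bmd, scan$mask, erosion_mm = erosion_mm)
    lm$patient_id <- row$patient_id
    per_level[[i]] <- lm
    agg <- aggregate_patient(lm, eligible_levels = vol_levels)
    agg$ct_abmd <- ct_abmd_patient(bmd, scan$mask, levels = areal_levels)
    agg$patient_id <- row$patient_id
    per_patient[[i]] <- agg
  }
  level_measures <- bind_rows(per_level)
  patient_measures <- bind_rows(per_patient)

  cohort <- left_join(cohort_in, patient_measures, by = "patient_id")
  audit <- NULL
  if ("exclusion" %in% names(cohort)) {
    res <- apply_exclusions(cohort)
    cohort <- res$analyzed
    audit <- res$audit
  }
  cohort <- cohort[!is.na(cohort$evaluable) & cohort$evaluable, , drop = FALSE]
  if (nrow(cohort) == 0) qct_data_error("no evaluable patients")

  stats_res <- run_stats(cohort, adjust = adjust)
  thresholds <- tryCatch(
    transfer_threshold(cohort, .data$fracture, .data$trabecular_vbmd,
                       .data$integral_vbmd),
    error = function(e) NULL
  )

  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(level_measures, file.path(out, "level_measures.csv"),
                   progress = FALSE)
  readr::write_csv(cohort, file.path(out, "cohort_analyzed.csv"),
                   progress = FALSE)
  jsonlite::write_json(stats_res, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(thresholds)) {
    jsonlite::write_json(thresholds, file.path(out, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(audit)) {
    readr::write_csv(audit, file.path(out, "exclusion_audit.csv"),
                     progress = FALSE)
  }
  writeLines(c(
    paste0("qctscreen version: ",
           as.character(utils::packageVersion("qctscreen"))),
    paste0("config hash: ",
           rlang::hash(config[setdiff(names(config), "output_dir")])),
    paste0("patients analyzed: ", nrow(cohort))
  ), file.path(out, "run_log.txt"))

  invisible(list(cohort = cohort, measures = level_measures,
                 stats = stats_res, thresholds = thresholds, audit = audit))
}
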