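#' Specify a synthetic two-group screening cohort
#'
#' Cohorts carry one row per patient with demographics, DXA measures and
#' CT-derived bone measures, split into a fractured and a non-fractured
#' group. Each measure is Gaussian within group; cross-measure dependence
#' comes from a single shared latent factor, giving every pair of measures
#' within-group correlation equal to `correlation`.
#'
#' The default group sizes (44 non-fractured / 148 fractured), group means
#' and SDs, and women fractions reproduce the study-group characteristics of
#' a prevalent-fracture QCT screening cohort: e.g. trabecular vBMD
#' 113.5 (34.3) vs 62.8 (27.5) mg/cm^3 and DXA aBMD 1.076 (0.219) vs
#' 0.948 (0.204) g/cm^2 for non-fractured vs fractured patients.
#'
#' @param n_nonfractured,n_fractured Group sizes (> 0).
#' @param measures Tibble with columns `measure`, `mean_nonfractured`,
#'   `sd_nonfractured`, `mean_fractured`, `sd_fractured`. Defaults to the
#'   reference values above.
#' @param women_fraction Length-2 named numeric (`nonfractured`,
#'   `fractured`) in `[0, 1]`.
#' @param correlation Shared-latent-factor level in `[0, 1)`; pairwise
#'   within-group correlation of all measures.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_nonfractured = 44L,
                        n_fractured = 148L,
                        measures = reference_cohort_measures(),
                        women_fraction = c(nonfractured = 34 / 44,
                                           fractured = 107 / 148),
                        correlation = 0.5,
                        seed = 1L) {
  if (n_nonfractured <= 0 || n_fractured <= 0) {
    qct_data_error("group sizes must be positive")
  }
  measures <- as_tibble(measures)
  need <- c("measure", "mean_nonfractured", "sd_nonfractured",
            "mean_fractured", "sd_fractured")
  stopifnot(all(need %in% names(measures)))
  if (any(measures$sd_nonfractured <= 0) || any(measures$sd_fractured <= 0)) {
    qct_data_error("measure SDs must be positive")
  }
  if (correlation < 0 || correlation >= 1) {
    qct_data_error("`correlation` must lie in [0, 1)")
  }
  if (any(women_fraction < 0 | women_fraction > 1)) {
    qct_data_error("`women_fraction` must lie in [0, 1]")
  }
  structure(
    list(n_nonfractured = as.integer(n_nonfractured),
         n_fractured = as.integer(n_fractured),
         measures = measures, women_fraction = women_fraction,
         correlation = correlation, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Reference group means and SDs for the synthetic cohort
#'
#' Per-measure group means (SDs) for the non-fractured (n = 44) and
#' fractured (n = 148) groups of the reference screening cohort. Units:
#' age in years, T-score in SD, aBMD in g/cm^2, vBMD in mg/cm^3, BMC in g.
#'
#' @return A tibble with one row per measure.
#' @export
reference_cohort_measures <- function() {
  tibble(
    measure = c("age", "dxa_tscore", "dxa_abmd", "ct_abmd", "manual_vbmd",
                "trabecular_vbmd", "integral_vbmd", "bmc"),
    mean_nonfractured = c(64.3, -1.4, 1.076, 0.951, 119.7, 113.5, 188.0, 6.42),
    sd_nonfractured   = c(8.6, 1.6, 0.219, 0.204, 38.1, 34.3, 35.5, 1.87),
    mean_fractured    = c(72.0, -2.4, 0.948, 0.752, 58.4, 62.8, 140.2, 5.00),
    sd_fractured      = c(9.3, 1.6, 0.204, 0.199, 32.7, 27.5, 32.1, 1.68)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws a patient table from a [cohort_spec()]: per group, each measure is
#' Gaussian with the specified mean/SD, all measures share a latent factor
#' inducing pairwise correlation `spec$correlation`, and sex is Bernoulli
#' with the group's women fraction.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `patient_id`, `fracture` (logical), `sex`
#'   (`"F"`/`"M"`) and one column per measure.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(co, fracture)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    draw_group <- function(n, fractured, wf) {
      z <- rnorm(n)
      rho <- spec$correlation
      cols <- purrr::pmap(spec$measures, function(measure,
                                                  mean_nonfractured,
                                                  sd_nonfractured,
                                                  mean_fractured,
                                                  sd_fractured) {
        m <- if (fractured) mean_fractured else mean_nonfractured
        s <- if (fractured) sd_fractured else sd_nonfractured
        m + s * (sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
      })
      names(cols) <- spec$measures$measure
      tibble(fracture = fractured,
             sex = ifelse(rbinom(n, 1, wf) == 1, "F", "M"),
             !!!cols)
    }
    out <- bind_rows(
      draw_group(spec$n_nonfractured, FALSE,
                 spec$women_fraction[["nonfractured"]]),
      draw_group(spec$n_fractured, TRUE,
                 spec$women_fraction[["fractured"]])
    )
    mutate(out, patient_id = seq_len(nrow(out)), .before = 1)
  })
}

# cascade criteria, in the order they are applied
exclusion_criteria <- function() {
  c("metastasis_hematologic", "no_assessable_dxa", "no_assessable_ct",
    "age_below_50", "insufficient_coverage_nonfractured")
}

#' Build a patient roster with exclusion flags
#'
#' Builds a roster of `n_initial` patients carrying at most one exclusion
#' flag each, following the screening cascade: (1) history of vertebral
#' metastasis or hematologic disorder, (2) no assessable lumbar DXA, (3) no
#' assessable CT, (4) age below 50 at DXA, and (5) non-fractured patients
#' without sufficient spine coverage (T7-L4) for fracture exclusion. The
#' remaining patients are the analyzed group; `n_fractured_analyzed` of them
#' are flagged as having at least one prevalent vertebral fracture.
#'
#' @param counts Named non-negative integers, one per criterion (names as in
#'   the cascade above). Defaults to the reference cascade
#'   (18, 34, 15, 35, 66 out of 360).
#' @param n_initial Initial roster size.
#' @param n_fractured_analyzed Number of analyzed patients with prevalent
#'   fracture.
#' @return Tibble `patient_id`, `exclusion` (ordered factor, `NA` =
#'   analyzed), `fracture` (logical, `NA` for excluded patients).
#' @examples
#' roster <- build_exclusion_roster()
#' sum(is.na(roster$exclusion))
#' @export
build_exclusion_roster <- function(counts = c(metastasis_hematologic = 18,
                                              no_assessable_dxa = 34,
                                              no_assessable_ct = 15,
                                              age_below_50 = 35,
                                              insufficient_coverage_nonfractured = 66),
                                   n_initial = 360,
                                   n_fractured_analyzed = 148) {
  crit <- exclusion_criteria()
  counts <- counts[intersect(names(counts), crit)]
  full <- setNames(rep(0L, length(crit)), crit)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) qct_data_error("exclusion counts must be non-negative")
  pool <- n_initial
  for (k in crit) {
    if (full[[k]] > pool) {
      qct_data_error(paste0("exclusion count for '", k,
                            "' exceeds the remaining pool"))
    }
    pool <- pool - full[[k]]
  }
  if (n_fractured_analyzed > pool) {
    qct_data_error("more fractured patients than analyzed patients")
  }
  exclusion <- factor(rep(c(crit, NA), times = c(full, pool)), levels = crit)
  fracture <- rep(NA, n_initial)
  analyzed <- which(is.na(exclusion))
  fracture[analyzed] <- c(rep(TRUE, n_fractured_analyzed),
                          rep(FALSE, pool - n_fractured_analyzed))
  tibble(patient_id = seq_len(n_initial), exclusion = exclusion,
         fracture = fracture)
}

#' Apply the exclusion cascade with an audit trail
#'
#' Sequentially removes flagged patients in cascade order and records how
#' many left at each step. The audit satisfies
#' `n analyzed + sum(removed) == initial roster size`.
#'
#' @param roster Tibble with `patient_id` and `exclusion` columns (as from
#'   [build_exclusion_roster()], or any table using the same flag names).
#' @return `list(analyzed = tibble, audit = tibble)`; the audit has one row
#'   per criterion with `n_removed` and `n_remaining`.
#' @export
apply_exclusions <- function(roster) {
  if (!all(c("patient_id", "exclusion") %in% names(roster))) {
    qct_data_error("roster must have `patient_id` and `exclusion` columns")
  }
  crit <- exclusion_criteria()
  bad <- setdiff(unique(as.character(roster$exclusion)), c(crit, NA))
  if (length(bad) > 0) {
    qct_data_error(paste0("unknown exclusion flags: ",
                          paste(bad, collapse = ", ")))
  }
  remaining <- roster
  audit <- vector("list", length(crit))
  for (i in seq_along(crit)) {
    drop <- !is.na(remaining$exclusion) &
      as.character(remaining$exclusion) == crit[i]
    audit[[i]] <- tibble(criterion = crit[i], n_removed = sum(drop),
                         n_remaining = nrow(remaining) - sum(drop))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  list(analyzed = as_tibble(remaining), audit = bind_rows(audit))
}
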