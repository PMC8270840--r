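#' Diagnostic vBMD threshold pairs
#'
#' A threshold pair classifies a volumetric BMD into osteoporosis, low bone
#' mass, or normal. The reference trabecular-vBMD bands follow the ACR
#' convention: osteoporosis below 80 mg/cm^3, low bone mass for
#' 80 <= BMD <= 120 (upper bound inclusive). Transferred bands (e.g. for
#' integral vBMD) use a half-open low-bone-mass band `[low, high)`, matching
#' the published integral bands osteoporosis < 160 and 160 <= BMD < 190.
#'
#' @param measure Measure name the thresholds apply to.
#' @param osteoporosis Osteoporosis cutoff (mg/cm^3, exclusive upper bound
#'   of the osteoporosis band).
#' @param low_bone_mass Upper cutoff of the low-bone-mass band (mg/cm^3).
#' @param provenance `"reference"` (upper bound inclusive) or
#'   `"transferred"` (half-open band).
#' @param low_upper_inclusive Override the band-closure convention.
#' @return A `diagnostic_thresholds` object.
#' @examples
#' classify_band(c(70, 80, 120, 121), acr_trabecular_thresholds())
#' @export
diagnostic_thresholds <- function(measure, osteoporosis, low_bone_mass,
                                  provenance = c("reference", "transferred"),
                                  low_upper_inclusive = NULL) {
  provenance <- match.arg(provenance)
  if (osteoporosis >= low_bone_mass) {
    qct_data_error("osteoporosis cutoff must lie below the low-bone-mass cutoff")
  }
  structure(
    list(measure = measure, osteoporosis = osteoporosis,
         low_bone_mass = low_bone_mass, provenance = provenance,
         low_upper_inclusive = low_upper_inclusive %||%
           (provenance == "reference")),
    class = "diagnostic_thresholds"
  )
}

#' @rdname diagnostic_thresholds
#' @export
acr_trabecular_thresholds <- function() {
  diagnostic_thresholds("trabecular_vbmd", 80, 120, provenance = "reference")
}

#' @rdname diagnostic_thresholds
#' @param value vBMD value(s), mg/cm^3.
#' @param thresholds A `diagnostic_thresholds` object.
#' @export
classify_band <- function(value, thresholds) {
  stopifnot(inherits(thresholds, "diagnostic_thresholds"))
  low_hit <- if (thresholds$low_upper_inclusive) {
    value <= thresholds$low_bone_mass
  } else {
    value < thresholds$low_bone_mass
  }
  out <- ifelse(value < thresholds$osteoporosis, "osteoporosis",
                ifelse(low_hit, "low bone mass", "normal"))
  factor(out, levels = c("osteoporosis", "low bone mass", "normal"))
}

#' @export
print.diagnostic_thresholds <- function(x, ...) {
  up <- if (x$low_upper_inclusive) "]" else ")"
  cat("<diagnostic_thresholds> ", x$measure, " (", x$provenance, "): ",
      "osteoporosis < ", x$osteoporosis, "; low bone mass [",
      x$osteoporosis, ", ", x$low_bone_mass, up, " mg/cm^3\n", sep = "")
  invisible(x)
}

#' Transfer a diagnostic cutoff between bone measures via ROC distance
#'
#' Derives a cutoff for a target measure (e.g. integral vBMD) from a
#' reference cutoff of another measure (e.g. the ACR trabecular-vBMD
#' cutoffs) on the same subjects: the reference cutoff's
#' (sensitivity, specificity) point is computed, every candidate threshold
#' on the target measure's ROC curve is scanned, and the candidate whose
#' (sensitivity, specificity) point has the smallest Euclidean distance to
#' the reference point is returned, rounded half-away-from-zero to the
#' nearest `rounding_step`. Ties in distance are broken toward higher
#' specificity (fewer false positives in a screening setting), then toward
#' the lower cutoff.
#'
#' Both measures are taken with `direction = "<"` semantics: values below
#' the cutoff test positive.
#'
#' @param data Data frame with outcome and both measures.
#' @param truth Column (unquoted) with binary fracture status.
#' @param reference,target Columns (unquoted) with the reference and target
#'   measures.
#' @param reference_cutoffs Numeric vector of reference cutoffs to transfer
#'   (default the ACR trabecular pair 80 and 120 mg/cm^3).
#' @param rounding_step Rounding step in mg/cm^3 (default 5); `0` disables
#'   rounding.
#' @return Tibble with one row per reference cutoff: the transferred cutoff
#'   (raw and rounded), the matched sensitivity/specificity (percent) of
#'   both measures, and the minimized ROC distance.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 5))
#' transfer_threshold(co, fracture, trabecular_vbmd, integral_vbmd)
#' @export
transfer_threshold <- function(data, truth, reference, target,
                               reference_cutoffs = c(80, 120),
                               rounding_step = 5) {
  y <- as_event(dplyr::pull(data, {{ truth }}))
  ref <- dplyr::pull(data, {{ reference }})
  tgt <- dplyr::pull(data, {{ target }})
  ok <- !is.na(y) & !is.na(ref) & !is.na(tgt)
  y <- y[ok]; ref <- ref[ok]; tgt <- tgt[ok]
  if (!any(y) || all(y)) {
    qct_data_error("both outcome classes must be present")
  }
  if (length(unique(tgt)) < 2) {
    qct_data_error("target measure is constant: no ROC points to scan")
  }
  # candidate target thresholds: midpoints between adjacent distinct values,
  # plus sentinels just beyond the observed range
  ut <- sort(unique(tgt))
  gaps <- diff(ut)
  cand <- c(ut[1] - (if (length(gaps)) gaps[1] else 1) / 2,
            ut[-length(ut)] + gaps / 2,
            ut[length(ut)] + (if (length(gaps)) gaps[length(gaps)] else 1) / 2)
  sens_t <- vapply(cand, function(t) mean(tgt[y] < t), numeric(1))
  spec_t <- vapply(cand, function(t) mean(tgt[!y] >= t), numeric(1))

  rows <- lapply(reference_cutoffs, function(rc) {
    sr <- mean(ref[y] < rc)
    pr <- mean(ref[!y] >= rc)
    d2 <- (sens_t - sr)^2 + (spec_t - pr)^2
    best <- which(d2 == min(d2))
    if (length(best) > 1) {
      best <- best[order(-spec_t[best], cand[best])][1]
    }
    raw <- cand[best]
    tibble(
      reference_cutoff = rc,
      target_cutoff_raw = raw,
      target_cutoff = round_to_step(raw, rounding_step),
      sensitivity_reference = 100 * sr,
      specificity_reference = 100 * pr,
      sensitivity_target = 100 * sens_t[best],
      specificity_target = 100 * spec_t[best],
      distance = sqrt(d2[best])
    )
  })
  bind_rows(rows)
}

# round half away from zero to the nearest multiple of `step`
round_to_step <- function(x, step) {
  if (step == 0) return(x)
  sign(x) * floor(abs(x) / step + 0.5) * step
}
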