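#' ROC curve with DeLong variance
#'
#' Builds the empirical ROC curve of a bone measure against fracture status.
#' The AUC is the Mann-Whitney concordance probability with ties counted as
#' half; its variance is the DeLong structural-components estimate, and the
#' 95% CI is the normal approximation clipped to `[0, 1]`. Thresholds are
#' placed at midpoints between adjacent distinct values (plus sentinels
#' below/above the range). With `direction = "<"` (the default for bone
#' measures) lower values indicate fracture, and a subject tests positive at
#' threshold `t` when `value < t`.
#'
#' @param data Data frame with one row per subject.
#' @param truth Column (unquoted) with the binary outcome; logical, or any
#'   two-level vector whose larger level (`TRUE`, second factor level) is the
#'   event.
#' @param score Column (unquoted) with the continuous measure.
#' @param direction `"<"` if lower values indicate the event (risk
#'   orientation for bone measures), `">"` otherwise.
#' @return A `qct_roc` object; see [tidy.qct_roc()] / [glance.qct_roc()].
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 3))
#' r <- roc_curve(co, fracture, trabecular_vbmd)
#' glance(r)
#' @export
roc_curve <- function(data, truth, score, direction = "<") {
  y <- as_event(dplyr::pull(data, {{ truth }}))
  x <- dplyr::pull(data, {{ score }})
  direction <- match.arg(direction, c("<", ">"))
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2) {
    qct_data_error("AUC undefined: both outcome classes must be present")
  }
  s <- if (direction == "<") -x else x   # oriented: higher = higher risk
  comp <- delong_components(s[y], s[!y])
  curve <- roc_points(y, x, direction)
  se <- sqrt(comp$var)
  structure(
    list(curve = curve, auc = comp$auc, auc_var = comp$var,
         ci = pmin(pmax(comp$auc + c(-1, 1) * qnorm(0.975) * se, 0), 1),
         direction = direction, n_cases = sum(y), n_controls = sum(!y)),
    class = "qct_roc"
  )
}

# accepts logical, factor, 0/1, or two-level character
as_event <- function(y) {
  if (is.logical(y)) return(y)
  if (is.numeric(y) && all(y %in% c(0, 1), na.rm = TRUE)) return(y == 1)
  f <- as.factor(y)
  if (nlevels(f) != 2) {
    qct_data_error("outcome must be binary")
  }
  f == levels(f)[2]
}

# Mann-Whitney AUC (ties = 1/2) and DeLong structural components
delong_components <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  psi <- outer(cases, controls,
               function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)           # per-case components
  v01 <- colMeans(psi)           # per-control components
  auc <- mean(psi)
  v <- if (m > 1) var(v10) / m else 0
  w <- if (n > 1) var(v01) / n else 0
  list(auc = auc, var = v + w, v10 = v10, v01 = v01)
}

roc_points <- function(y, x, direction) {
  ux <- sort(unique(x))
  mids <- if (length(ux) > 1) (head(ux, -1) + tail(ux, -1)) / 2 else numeric(0)
  thr <- c(-Inf, mids, Inf)
  pos <- if (direction == "<") {
    function(t) x < t
  } else {
    function(t) x > t
  }
  sens <- vapply(thr, function(t) mean(pos(t)[y]), numeric(1))
  spec <- vapply(thr, function(t) mean(!pos(t)[!y]), numeric(1))
  tibble(threshold = thr, sensitivity = sens, specificity = spec) |>
    arrange(dplyr::desc(.data$specificity), .data$sensitivity)
}

#' @rdname tidiers
#' @method tidy qct_roc
#' @export
tidy.qct_roc <- function(x, ...) x$curve

#' @rdname tidiers
#' @method glance qct_roc
#' @export
glance.qct_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_var = x$auc_var,
         ci_low = x$ci[1], ci_high = x$ci[2],
         n_cases = x$n_cases, n_controls = x$n_controls,
         direction = x$direction)
}

#' @export
print.qct_roc <- function(x, ...) {
  cat("<qct_roc> AUC ", sprintf("%.3f", x$auc), " (95% CI ",
      sprintf("%.3f", x$ci[1]), "-", sprintf("%.3f", x$ci[2]), "), ",
      x$n_cases, " cases / ", x$n_controls, " controls\n", sep = "")
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two measures taken on the same subjects using the
#' paired DeLong structural-components covariance and a two-sided normal
#' test. Identical (or rank-identical) score vectors give an AUC difference
#' of 0 and p = 1.
#'
#' @inheritParams roc_curve
#' @param score_a,score_b Columns (unquoted) with the two measures.
#' @param direction_a,direction_b Risk orientation per measure, as in
#'   [roc_curve()].
#' @return A `qct_delong` object; `glance()` gives a one-row summary.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 3))
#' dl <- delong_test(co, fracture, trabecular_vbmd, dxa_abmd)
#' glance(dl)
#' @export
delong_test <- function(data, truth, score_a, score_b,
                        direction_a = "<", direction_b = "<") {
  y <- as_event(dplyr::pull(data, {{ truth }}))
  a <- dplyr::pull(data, {{ score_a }})
  b <- dplyr::pull(data, {{ score_b }})
  ok <- !is.na(y) & !is.na(a) & !is.na(b)
  y <- y[ok]; a <- a[ok]; b <- b[ok]
  if (length(unique(y)) < 2) {
    qct_data_error("DeLong test undefined: both outcome classes required")
  }
  sa <- if (direction_a == "<") -a else a
  sb <- if (direction_b == "<") -b else b
  ca <- delong_components(sa[y], sa[!y])
  cb <- delong_components(sb[y], sb[!y])
  m <- sum(y); n <- sum(!y)
  cov10 <- if (m > 1) stats::cov(ca$v10, cb$v10) / m else 0
  cov01 <- if (n > 1) stats::cov(ca$v01, cb$v01) / n else 0
  vdiff <- ca$var + cb$var - 2 * (cov10 + cov01)
  diff <- ca$auc - cb$auc
  if (vdiff <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(diff) < sqrt(.Machine$double.eps)) 1 else 0
  } else {
    z <- diff / sqrt(vdiff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(auc_a = ca$auc, auc_b = cb$auc, auc_diff = diff,
         var_diff = max(vdiff, 0), statistic = z, p_value = p),
    class = "qct_delong"
  )
}

#' @rdname tidiers
#' @method glance qct_delong
#' @export
glance.qct_delong <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, auc_diff = x$auc_diff,
         statistic = x$statistic, p_value = x$p_value)
}

#' @export
print.qct_delong <- function(x, ...) {
  cat("<qct_delong> AUC ", sprintf("%.3f", x$auc_a), " vs ",
      sprintf("%.3f", x$auc_b), ", z = ", sprintf("%.3f", x$statistic),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Sensitivity and specificity at a diagnostic cutoff
#'
#' For `direction = "<"` (lower is abnormal): sensitivity is the percentage
#' of fractured subjects below the cutoff; specificity the percentage of
#' non-fractured subjects at or above it.
#'
#' @inheritParams roc_curve
#' @param cutoff Diagnostic cutoff on the measure's own scale.
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity` (percent).
#' @export
sens_spec_at <- function(data, truth, score, cutoff, direction = "<") {
  y <- as_event(dplyr::pull(data, {{ truth }}))
  x <- dplyr::pull(data, {{ score }})
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (!any(y) || all(y)) {
    qct_data_error("sensitivity/specificity undefined: empty outcome class")
  }
  stopifnot(is.finite(cutoff))
  pos <- if (direction == "<") x < cutoff else x > cutoff
  tibble(cutoff = cutoff,
         sensitivity = 100 * mean(pos[y]),
         specificity = 100 * mean(!pos[!y]))
}
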