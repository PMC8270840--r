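#' Standardize a measure to per-SD units
#'
#' Centers and scales by the whole-sample mean and SD so that logistic
#' coefficients are per one-SD change. With `flip = TRUE` (the convention
#' for bone measures) the sign is reversed, so an odds ratio above 1 means
#' greater fracture odds per SD *decrease* of the measure.
#'
#' @param x Numeric vector.
#' @param flip Reverse the sign after standardizing.
#' @return Numeric vector of z-scores.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x, flip = FALSE) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    qct_data_error("degenerate predictor: zero variance")
  }
  z <- (x - mean(x, na.rm = TRUE)) / s
  if (flip) -z else z
}

#' Fracture-association odds ratio per SD change
#'
#' Maximum-likelihood logistic regression of fracture status on a
#' standardized (and, for bone measures, risk-oriented) predictor, with
#' optional covariate adjustment. Reports the odds ratio per one-SD change
#' with a Wald 95% CI. Perfect or quasi-perfect separation is flagged and no
#' estimate is reported.
#'
#' @param data Data frame, one row per subject.
#' @param outcome Column (unquoted) with binary fracture status.
#' @param predictor Column (unquoted) with the measure.
#' @param adjust Character vector of covariate column names (e.g.
#'   `c("age", "sex")`), or `NULL` for the crude model.
#' @param flip Risk orientation of the predictor; `TRUE` for bone measures
#'   (OR per SD decrease).
#' @return A `qct_or` object; `tidy()` gives per-term coefficients and ORs,
#'   `glance()` a one-row model summary.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 11))
#' glance(fracture_or(co, fracture, trabecular_vbmd, adjust = c("age", "sex")))
#' @export
fracture_or <- function(data, outcome, predictor, adjust = NULL,
                        flip = TRUE) {
  y <- as_event(dplyr::pull(data, {{ outcome }}))
  x <- dplyr::pull(data, {{ predictor }})
  df <- tibble(.y = y, .z = standardize(x, flip = flip))
  for (v in adjust) df[[v]] <- data[[v]]
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2) {
    qct_data_error("both outcome classes must be present")
  }
  form <- stats::as.formula(
    paste(".y ~ .z", if (length(adjust)) paste("+", paste(adjust, collapse = " + ")) else "")
  )
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- coef(fit)[".z"]
  se <- sqrt(diag(vcov(fit)))[".z"]
  separable <- sep_warn || !fit$converged || abs(beta) > 15
  structure(
    list(model = fit,
         estimate = if (separable) NA_real_ else unname(exp(beta)),
         conf_low = if (separable) NA_real_ else unname(exp(beta - qnorm(0.975) * se)),
         conf_high = if (separable) NA_real_ else unname(exp(beta + qnorm(0.975) * se)),
         adjusted = length(adjust) > 0, covariates = adjust,
         flip = flip, separable = separable,
         n = nrow(df), n_events = sum(df$.y)),
    class = "qct_or"
  )
}

#' Tidiers for fitted result objects
#'
#' broom-style `tidy()` and `glance()` methods for the package's fitted
#' objects (`qct_or`, `qct_roc`, `qct_delong`).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy qct_or
#' @export
tidy.qct_or <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"],
    or = exp(sm[, "Estimate"]),
    or_low = exp(sm[, "Estimate"] - qnorm(0.975) * sm[, "Std. Error"]),
    or_high = exp(sm[, "Estimate"] + qnorm(0.975) * sm[, "Std. Error"])
  )
}

#' @rdname tidiers
#' @method glance qct_or
#' @export
glance.qct_or <- function(x, ...) {
  tibble(or = x$estimate, ci_low = x$conf_low, ci_high = x$conf_high,
         adjusted = x$adjusted,
         covariates = paste(x$covariates %||% character(0), collapse = ","),
         separable = x$separable, n = x$n, n_events = x$n_events)
}

#' @export
print.qct_or <- function(x, ...) {
  if (x$separable) {
    cat("<qct_or> separation detected; no estimate\n")
  } else {
    cat("<qct_or> OR per SD ", if (x$flip) "decrease " else "increase ",
        sprintf("%.2f", x$estimate), " (95% CI ",
        sprintf("%.2f", x$conf_low), "-", sprintf("%.2f", x$conf_high),
        ")", if (x$adjusted) paste0(", adjusted for ",
                                    paste(x$covariates, collapse = ", ")),
        "\n", sep = "")
  }
  invisible(x)
}

#' Group comparison of cohort characteristics
#'
#' Compares every numeric measure between fractured and non-fractured
#' patients with Welch two-sample t tests, and sex (if present) with a
#' chi-squared test of independence. Output is shaped like a study-group
#' characteristics table: group means (SD) plus test statistic and p value.
#'
#' @param data Cohort tibble with a binary `fracture`-type column.
#' @param group Column (unquoted) defining the two groups.
#' @param vars Character vector of variables to compare; default all numeric
#'   columns except identifiers.
#' @return Tibble with one row per variable.
#' @export
group_compare <- function(data, group, vars = NULL) {
  g <- as_event(dplyr::pull(data, {{ group }}))
  vars <- vars %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    c("patient_id")
  )
  rows <- lapply(vars, function(v) {
    x0 <- data[[v]][!g]; x1 <- data[[v]][g]
    tt <- tryCatch(t.test(x0, x1), error = function(e) NULL)
    if (is.null(tt)) {    # essentially constant data
      tt <- list(statistic = NA_real_, parameter = NA_real_,
                 p.value = NA_real_)
    }
    tibble(variable = v,
           mean_nonfractured = mean(x0, na.rm = TRUE),
           sd_nonfractured = sd(x0, na.rm = TRUE),
           mean_fractured = mean(x1, na.rm = TRUE),
           sd_fractured = sd(x1, na.rm = TRUE),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, test = "welch_t")
  })
  out <- bind_rows(rows)
  if ("sex" %in% names(data)) {
    ct <- suppressWarnings(chisq.test(table(data$sex, g)))
    out <- bind_rows(out, tibble(
      variable = "sex",
      mean_nonfractured = mean(data$sex[!g] == "F"),
      sd_nonfractured = NA_real_,
      mean_fractured = mean(data$sex[g] == "F"),
      sd_fractured = NA_real_,
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value, test = "chi_squared"
    ))
  }
  out
}

#' Welch t test from group summary statistics
#'
#' Two-sample Welch t test computed from printed group means, SDs and sizes
#' (no raw data needed), with Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_summary(64.3, 8.6, 44, 72.0, 9.3, 148)
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  tibble(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pool two-group summaries into whole-cohort summaries
#'
#' Combines per-group means and SDs into the pooled (total-column) mean and
#' SD using exact moment algebra with the given group sizes.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (vectorized).
#' @return Tibble `mean`, `sd` of the pooled sample (SD uses the n-1
#'   denominator on the combined sample).
#' @examples
#' pool_groups(113.5, 34.3, 44, 62.8, 27.5, 148)
#' @export
pool_groups <- function(mean1, sd1, n1, mean2, sd2, n2) {
  n <- n1 + n2
  m <- (n1 * mean1 + n2 * mean2) / n
  ss <- (n1 - 1) * sd1^2 + (n2 - 1) * sd2^2 +
    n1 * (mean1 - m)^2 + n2 * (mean2 - m)^2
  tibble(mean = m, sd = sqrt(ss / (n - 1)))
}

#' Agreement analyses for paired measurement series
#'
#' `bland_altman()` reports the mean difference (bias) and 95% limits of
#' agreement `bias +/- 1.96 * SD(a - b)`; `r_squared()` the coefficient of
#' determination of the least-squares fit of `a` on `b`.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return `bland_altman()`: one-row tibble `bias`, `loa_low`, `loa_high`;
#'   `r_squared()`: scalar.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) qct_data_error("series must have equal length")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  tibble(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' @rdname bland_altman
#' @export
r_squared <- function(a, b) {
  if (length(a) != length(b)) qct_data_error("series must have equal length")
  # R^2 of the simple least-squares fit with intercept
  stats::cor(a, b)^2
}
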