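#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: ROC curves
#' (sensitivity against 1 - specificity with the AUC in the subtitle) and
#' virtual-DXA areal maps (raster of areal density over the projection
#' plane).
#'
#' @param object A `qct_roc` or `areal_map` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name qct-autoplot
NULL

#' @rdname qct-autoplot
#' @method autoplot qct_roc
#' @export
autoplot.qct_roc <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$ci[1], object$ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname qct-autoplot
#' @method autoplot areal_map
#' @export
autoplot.areal_map <- function(object, ...) {
  d <- dim(object$areal)
  df <- tidyr::expand_grid(i = seq_len(d[1]), k = seq_len(d[2]))
  df$x <- (df$i - 0.5) * object$pixel_spacing_mm[1]
  df$z <- (df$k - 0.5) * object$pixel_spacing_mm[2]
  df$areal <- object$areal[cbind(df$i, df$k)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$areal)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression(g / cm^2)) +
    ggplot2::labs(x = "Left-right (mm)", y = "Inferior-superior (mm)") +
    ggplot2::theme_minimal()
}

#' Forest plot of fracture-association odds ratios
#'
#' @param or_table Tibble as produced by [run_stats()]'s `or_table` (columns
#'   `measure`, `or`, `ci_low`, `ci_high`, `adjusted`).
#' @return A ggplot object.
#' @export
plot_or_forest <- function(or_table) {
  df <- dplyr::filter(or_table, !.data$separable)
  df$model <- ifelse(df$adjusted, "adjusted", "crude")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$measure,
                                   colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per SD decrease (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
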