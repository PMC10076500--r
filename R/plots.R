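# ggplot2 views of the main result types.

#' Boxplot of methylated-site proportions by codon fold class
#'
#' @param fold_tab Tibble from [fold_methylation_proportions()] (with a
#'   `sex` or `sample` column for colouring).
#' @param colour_by Column mapped to fill (default "sex").
#' @return A ggplot.
#' @export
plot_fold_methylation <- function(fold_tab, colour_by = "sex") {
  ggplot2::ggplot(fold_tab, ggplot2::aes(
    x = .data$fold_class, y = .data$proportion,
    fill = if (colour_by %in% names(fold_tab)) .data[[colour_by]] else NULL
  )) +
    ggplot2::geom_boxplot(outlier.colour = "black") +
    ggplot2::labs(x = "codon degeneracy (fold class)",
                  y = "proportion of sites methylated",
                  fill = colour_by) +
    ggplot2::theme_minimal()
}

#' Mean methylation level per genomic feature
#'
#' @param feature_w Tibble with feature, group, w (as produced by the
#'   pipeline's calling stage).
#' @return A ggplot.
#' @export
plot_feature_methylation <- function(feature_w) {
  ggplot2::ggplot(feature_w, ggplot2::aes(
    x = .data$feature, y = .data$w, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "weighted methylation level",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of per-CpG differential methylation
#'
#' @param dm_cpgs Tibble from [call_dm_cpgs()].
#' @return A ggplot of methylation difference against -log10 q, DM CpGs
#'   highlighted.
#' @export
plot_dm_volcano <- function(dm_cpgs) {
  ggplot2::ggplot(dm_cpgs, ggplot2::aes(
    x = .data$meth_diff, y = -log10(pmax(.data$q_value, 1e-300)),
    colour = .data$dm
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "methylation difference (percentage points)",
                  y = expression(-log[10] ~ q), colour = "DM") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::theme_minimal()
}

#' @describeIn methylation_vs_pnps Scatter of methylation level against
#'   pN/pS with the fitted line.
#' @param object A `meth_selection_fit`.
#' @export
autoplot.meth_selection_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data[[object$ratio_col]], y = .data[[object$w_col]]
  )) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = stats::coef(object$fit)[1],
                         slope = stats::coef(object$fit)[2],
                         colour = "firebrick") +
    ggplot2::labs(x = "pN/pS", y = "weighted methylation level") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_beta_regression Coefficient dot-and-interval plot.
#' @param object A `beta_reg` object.
#' @export
autoplot.beta_reg <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    ), height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "estimate (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}
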