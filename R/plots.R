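#' Volcano plot of differential-expression statistics
#'
#' Plots mean log2 difference against -log10 t-test p, highlighting the
#' features retained by the marker gates.
#'
#' @param stats A [diff_stats()] tibble.
#' @param thresholds A [marker_thresholds()] object used for highlighting.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, thresholds = marker_thresholds()) {
  markers <- select_markers(stats, thresholds)
  df <- stats %>%
    mutate(selected = .data$feature_id %in% markers$feature_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_log2_diff,
                                   y = -log10(.data$t_p),
                                   color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(log2(thresholds$fc_down),
                                       log2(thresholds$fc_up)),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                name = "marker") +
    ggplot2::labs(x = "Mean log2 difference (tumor - normal)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Centroid-correlation plot of nearest-centroid predictions
#'
#' Scatter of each sample's correlation with the normal centroid against
#' its correlation with the tumor centroid, colored by predicted class;
#' points below the diagonal are predicted tumor.
#'
#' @param predictions Tibble from [classify_cohort()].
#' @return A ggplot object.
#' @export
plot_centroid_correlations <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$r_tumor, y = .data$r_normal,
                               color = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Correlation with tumor centroid",
                  y = "Correlation with normal centroid") +
    ggplot2::theme_minimal()
}
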