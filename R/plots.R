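#' Plot quantification curves along the threshold filtration
#'
#' Line plots of LAA%, `nb0` and `nb1` against the HU threshold, one facet
#' per quantity (free y scales), coloured by slice when several slices are
#' present — the per-slice filtration profile.
#'
#' @param object An `heq_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heq_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = dplyr::all_of(c("laa_pct", "nb0", "nb1")),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, levels = c("laa_pct", "nb0", "nb1"),
                          labels = c("LAA%", "nb0", "nb1"))
  aes <- if ("slice_id" %in% names(long)) {
    ggplot2::aes(x = .data$threshold_hu, y = .data$value,
                 colour = .data$slice_id, group = .data$slice_id)
  } else {
    ggplot2::aes(x = .data$threshold_hu, y = .data$value)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Threshold (HU)", y = NULL,
                  title = "Emphysema quantification along the HU filtration") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated confusion matrix
#'
#' Heatmap of the 6 x 6 contingency table of true visual score against
#' prediction, annotated with counts.
#'
#' @param object An `heq_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heq_cv <- function(object, ...) {
  tab <- contingency_table(object)
  df <- tibble::as_tibble(as.table(tab))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(as.character(0:5))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted score", y = "Visual score",
                  title = sprintf("LOPO CV confusion matrix (accuracy %.1f%%)",
                                  100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a threshold range sweep as a triangular accuracy table
#'
#' Tile plot of best cross-validated accuracy per (lower, upper) threshold
#' range cell, the graphical analogue of the lower-triangular accuracy
#' tables.
#'
#' @param sweep Tibble from [range_sweep()].
#' @return A ggplot object.
#' @export
plot_range_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data$lower_hu),
                                      y = factor(.data$upper_hu),
                                      fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    100 * .data$accuracy))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "Lower threshold limit (HU)",
                  y = "Upper threshold limit (HU)",
                  title = "Best LOPO accuracy per threshold range") +
    ggplot2::theme_minimal()
}
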