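#' Stacked locus-frequency bar chart
#'
#' The clonal-frequency display: one bar per sample, filled by locus
#' call (including ND).
#'
#' @param freqs Locus-frequency tibble from [summarize_assignments()].
#' @return A ggplot object.
#' @export
plot_locus_frequencies <- function(freqs) {
  d <- freqs[!is.na(freqs$fraction), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                  fill = .data$call)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = NULL, y = "clonal frequency", fill = "locus") +
    ggplot2::theme_minimal()
}

#' Heatmap of a row-standardised expression matrix
#'
#' @param z Matrix from [expression_matrix_for_heatmap()].
#' @return A ggplot object (tile heatmap, red = over-, blue =
#'   under-expressed).
#' @export
plot_expression_heatmap <- function(z) {
  d <- as_tibble(as.data.frame.table(z, responseName = "z"))
  names(d)[1:2] <- c("feature", "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$feature,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a correlation report
#'
#' r-squared per gene with the selection cutoff line.
#'
#' @param object A `correlation_report` from
#'   [select_correlated_genes()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.correlation_report <- function(object, ...) {
  d <- object[!object$undefined, , drop = FALSE]
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_squared, y = .data$feature,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff"),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(r^2), y = NULL,
                  fill = sprintf("r² ≥ %.2f",
                                 attr(object, "cutoff"))) +
    ggplot2::theme_minimal()
}

#' Plot per-sample diversity
#'
#' @param object A tibble from [diversity_summary()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_diversity <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$pct_div_vs_prototype)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "% diversity vs prototype") +
    ggplot2::theme_minimal()
}
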