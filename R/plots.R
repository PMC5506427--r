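#' Per-sample feature histograms
#'
#' Overlaid density-normalised histograms of one feature per sample, with
#' optional gate cutoff lines — the standard view for checking a
#' control-referenced threshold (e.g. `bf_mean_pixel` of unstained vs
#' stained samples).
#'
#' @param table Feature table.
#' @param feature Feature column name.
#' @param cutoffs Optional numeric vector of cutoff(s) drawn as vertical
#'   lines.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_feature_hist <- function(table, feature, cutoffs = NULL, bins = 60) {
  p <- ggplot2::ggplot(table,
                       ggplot2::aes(x = .data[[feature]],
                                    fill = .data$sample_id)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, alpha = 0.55, position = "identity") +
    ggplot2::labs(x = feature, y = "density", fill = "sample") +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs))
    p <- p + ggplot2::geom_vline(xintercept = cutoffs, linetype = "dashed")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gating result
#'
#' Percent-of-parent per gate and sample as a grouped bar chart.
#'
#' @param object A `gating_result`.
#' @param gates Optional subset of gate names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gating_result <- function(object, gates = NULL, ...) {
  df <- object$counts
  if (!is.null(gates)) df <- df[df$gate %in% gates, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gate, y = .data$percent,
                                   fill = .data$sample_id)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "% of parent gate", fill = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.gating_result
#' @export
autoplot.senescan_run <- function(object, gates = NULL, ...) {
  autoplot(object$result, gates = gates, ...)
}

#' Show one cell's channel images
#'
#' Quick-look panel of a cell record's channels (grayscale, shared origin).
#'
#' @param cell A [cell_record()].
#' @param channels Optional channel subset.
#' @return A ggplot object.
#' @export
plot_cell <- function(cell, channels = NULL) {
  chans <- channels %||% names(cell$channels)
  df <- map_dfr(chans, function(ch) {
    m <- cell$channels[[ch]]
    tibble(channel = ch,
           row = as.vector(row(m)), col = as.vector(col(m)),
           value = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = cell$cell_id, x = NULL, y = NULL, fill = "counts") +
    ggplot2::theme_void()
}
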