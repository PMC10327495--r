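# ggplot2 views of the main result types.

#' Histogram of block lengths in a pangraph
#' @param graph A `pangraph`.
#' @param bins Number of bins (default 40).
#' @return A ggplot object.
#' @export
plot_block_lengths <- function(graph, bins = 40L) {
  df <- tidy.pangraph(graph)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$core)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "pancontig consensus length (bp)", y = "count",
                  fill = "core") +
    ggplot2::theme_minimal()
}

#' Histogram of paired breakpoint displacements
#' @param displacement A tibble from [breakpoint_displacement()].
#' @param cfg A [metrics_config()] (threshold drawn as a vertical line).
#' @return A ggplot object.
#' @export
plot_breakpoint_displacement <- function(displacement,
                                         cfg = metrics_config()) {
  d <- unlist(displacement$displacements, use.names = FALSE)
  df <- tibble::tibble(displacement = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement + 1)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = cfg$displacement_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "breakpoint displacement + 1 (bp)", y = "count") +
    ggplot2::theme_minimal()
}

#' Bar chart of partition-agreement fractions
#' @param comparison A tibble from [partition_compare()].
#' @return A ggplot object.
#' @export
plot_partition_compare <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$category, y = .data$fraction,
                               fill = .data$genome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of genome length") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pangraph <- function(object, ...) plot_block_lengths(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
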