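#' Plot an RMS topography on the electrode grid
#'
#' Tile map of per-channel RMS amplitude at grid positions; selected channels
#' can be highlighted.
#'
#' @param topo A tibble from [rms_topography()].
#' @param highlight Optional integer vector (or `channel_selection`) of
#'   channels to outline.
#' @return A ggplot object.
#' @export
plot_topography <- function(topo, highlight = NULL) {
  p <- ggplot2::ggplot(topo, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$rms)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_y_reverse(breaks = unique(topo$row)) +
    ggplot2::scale_x_continuous(breaks = unique(topo$col)) +
    ggplot2::scale_fill_viridis_c(name = "RMS") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  title = "Spatial RMS map") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    ch <- if (inherits(highlight, "channel_selection")) highlight$channel
          else as.integer(highlight)
    sub <- topo[topo$channel %in% ch, ]
    p <- p + ggplot2::geom_tile(data = sub, fill = NA, color = "red",
                                linewidth = 1)
  }
  p
}

#' Plot a confusion matrix
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot heat map, true class in rows, predicted in columns,
#'   annotated with counts.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "white", high = "seagreen") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = paste0(object$model, " confusion (",
                                 object$k, "-fold CV)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot accuracy against the number of selected channels
#'
#' @param sweep A tibble from [channel_sweep()].
#' @return A ggplot line chart, one line per classifier.
#' @export
plot_channel_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_channels,
                                      y = .data$accuracy,
                                      color = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(sweep$n_channels)) +
    ggplot2::labs(x = "selected channels L'", y = "mean CV accuracy",
                  color = "classifier") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
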