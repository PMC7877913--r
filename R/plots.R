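#' Scatter plot of a metric space
#'
#' Two chosen axes of the per-transcript metric table (the 3D spaces are
#' explored as 2D projections; use [export_coordinates()] for external 3D
#' rendering).
#'
#' @param metric_table Tibble from [build_metric_table()].
#' @param x,y Metric column names (strings).
#' @param mode Which mode's rows to plot.
#' @param highlight Optional character vector of transcript ids drawn in
#'   color on top (e.g. a candidate list).
#' @return A ggplot object.
#' @export
plot_metric_space <- function(metric_table, x = "fS", y = "fN", mode = "SO",
                              highlight = NULL) {
  df <- metric_table[metric_table$mode == mode, , drop = FALSE]
  df$highlight <- df$transcript_id %in% (highlight %||% character(0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8, colour = "grey40") +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = df[df$highlight, , drop = FALSE],
      colour = "#d1495b", size = 1.6
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pipeline result
#'
#' fS vs fN (SO mode) with candidates colored by class label.
#'
#' @param object A `"sel_scan"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sel_scan
#' @export
autoplot.sel_scan <- function(object, ...) {
  df <- object$metric_table[object$metric_table$mode == "SO", , drop = FALSE]
  df <- dplyr::left_join(
    df,
    object$classes[, c("transcript_id", "label")],
    by = "transcript_id"
  )
  df$label[is.na(df$label)] <- "background"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fS, y = .data$fN, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::labs(x = "fS (silent fraction)", y = "fN (nonsense fraction)",
                  colour = "class") +
    ggplot2::theme_minimal()
}
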