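#' Heatmap of a relevance map
#'
#' Absolute relevance over time and input channels (or hidden units),
#' darker meaning more relevant — the time-resolved view of where the
#' model's attention sits within a window.
#'
#' @param object A `har_relevance` map.
#' @param layer `"input"` or `"hidden"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.har_relevance <- function(object, layer = c("input", "hidden"), ...) {
  layer <- match.arg(layer)
  df <- tidy(object, layer = layer) %>%
    dplyr::mutate(relevance = abs(.data$relevance))
  ggplot(df, aes(x = .data$t_index, y = .data$unit, fill = .data$relevance)) +
    geom_raster() +
    scale_fill_gradient(low = "white", high = "darkred", name = "|R|") +
    labs(
      x = "time step", y = NULL,
      title = sprintf("%s relevance, target class %d", object$arch, object$target)
    ) +
    theme_minimal()
}

#' Confusion-matrix tile plot
#'
#' @param object A `har_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.har_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$pct)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.1f%%\n(%d)", .data$pct, .data$n)), size = 3) +
    scale_y_reverse(breaks = unique(df$true)) +
    scale_x_continuous(breaks = unique(df$predicted)) +
    scale_fill_gradient(low = "white", high = "steelblue", name = "row %") +
    labs(x = "predicted class", y = "true class") +
    theme_minimal()
}

#' Quadrant scatter of signal dynamics vs model attention
#'
#' Each point is one (channel, class) pair, placed by its zero-crossing
#' rate and its high-relevance time-point count; dashed lines mark the
#' thresholds used for quadrant assignment.
#'
#' @param points A [quadrant_assign()] result.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(points) {
  thr <- attr(points, "thresholds")
  ggplot(points, aes(
    x = .data$zcr, y = .data$rel_count,
    shape = factor(.data$class), colour = .data$quadrant
  )) +
    geom_point(size = 3) +
    geom_vline(xintercept = thr[["zcr"]], linetype = "dashed") +
    geom_hline(yintercept = thr[["count"]], linetype = "dashed") +
    labs(
      x = "zero-crossing rate (Hz)", y = "high-relevance count",
      shape = "class", colour = NULL
    ) +
    theme_minimal()
}

#' Bar chart of global per-channel relevance
#'
#' @param accumulated An [accumulated_input_relevance()] tibble, or any
#'   tibble with `channel` and `relevance` columns.
#' @return A ggplot object.
#' @export
plot_global_relevance <- function(accumulated) {
  ggplot(accumulated, aes(
    x = stats::reorder(.data$channel, -.data$relevance),
    y = .data$relevance, fill = .data$relevance
  )) +
    geom_col() +
    scale_fill_gradient(low = "grey80", high = "darkred", guide = "none") +
    labs(x = NULL, y = "share of total relevance") +
    theme_minimal()
}

#' Heatmap of class-conditional hidden-unit relevance
#'
#' @param object A `hidden_relevance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hidden_relevance <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::mutate(unit = factor(.data$unit, levels = rev(rownames(object$values))))
  ggplot(df, aes(x = factor(.data$class), y = .data$unit, fill = .data$relevance)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$relevance)), size = 3) +
    scale_fill_gradient(low = "white", high = "darkred", name = "share") +
    labs(x = "class", y = "hidden unit") +
    theme_minimal()
}
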