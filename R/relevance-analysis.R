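#' Zero-crossing rate of a signal
#'
#' Counts strict sign changes between consecutive samples — zeros continue
#' the previous sign, so touching zero without crossing does not count —
#' and divides by the signal duration.
#'
#' @param x Numeric vector (one channel's samples).
#' @param fs Sampling rate in Hz.
#' @return Crossings per second (Hz).
#' @export
#' @examples
#' zero_crossing_rate(sin(2 * pi * 2 * (0:299) / 100 + pi / 4), fs = 100) # 4 Hz
zero_crossing_rate <- function(x, fs) {
  if (length(x) < 2) abort("need at least 2 samples.")
  s <- sign(x)
  s <- s[s != 0]
  n_cross <- if (length(s) < 2) 0L else sum(diff(s) != 0)
  n_cross / (length(x) / fs)
}

#' Count high-relevance time points per channel
#'
#' Thresholds a temporally normalized relevance map at the given quantile
#' of all (unit, time) values jointly — the default keeps the top 30% —
#' and counts, per channel, the time points strictly above the threshold.
#' Sparsifying this way highlights the most informative signal segments.
#'
#' @param temporal A [normalize_temporal()] matrix.
#' @param quantile Threshold quantile (default 0.70).
#' @return Tibble with columns `channel` and `count`.
#' @export
relevance_count <- function(temporal, quantile = 0.70) {
  v <- as.vector(temporal)
  if (max(v) == min(v)) {
    warn("all relevance values equal; counts are all zero.")
    thr <- max(v)
  } else {
    thr <- stats::quantile(v, quantile, names = FALSE)
  }
  counts <- colSums(temporal > thr)
  ch <- colnames(temporal) %||% paste0("u", seq_len(ncol(temporal)))
  tibble(channel = ch, count = as.integer(counts))
}

#' Mean zero-crossing rate per (class, channel)
#'
#' @param data Long-format dataset tibble (raw, pre-normalization signals
#'   are the intended input).
#' @param fs Sampling rate in Hz.
#' @return Tibble with class, channel, zcr (the mean over the class's
#'   windows).
#' @export
zcr_by_class_channel <- function(data, fs = 100) {
  validate_har_data(data)
  data %>%
    tidyr::pivot_longer(dplyr::all_of(har_channels()),
      names_to = "channel", values_to = "x"
    ) %>%
    dplyr::arrange(.data$window_id, .data$t_index) %>%
    dplyr::group_by(.data$class, .data$channel, .data$window_id) %>%
    dplyr::summarise(zcr = zero_crossing_rate(.data$x, fs), .groups = "drop") %>%
    dplyr::group_by(.data$class, .data$channel) %>%
    dplyr::summarise(zcr = mean(.data$zcr), .groups = "drop")
}

#' Summed high-relevance counts per (class, channel)
#'
#' For each correctly classified sample, counts time points above the
#' top-relevance threshold per channel ([relevance_count()]) and sums the
#' counts within each true class.
#'
#' @param maps List of `har_relevance` maps, one per sample.
#' @param labels,predictions True and predicted class ids.
#' @param quantile Threshold quantile (default 0.70).
#' @return Tibble with class, channel, rel_count.
#' @export
relevance_counts_by_class <- function(maps, labels, predictions, quantile = 0.70) {
  correct <- which(labels == predictions)
  purrr::map(correct, function(s) {
    relevance_count(normalize_temporal(maps[[s]], "input"), quantile) %>%
      dplyr::mutate(class = labels[s])
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::group_by(.data$class, .data$channel) %>%
    dplyr::summarise(rel_count = sum(.data$count), .groups = "drop")
}

#' Join dynamics and attention into quadrant points
#'
#' @param zcr_tbl Output of [zcr_by_class_channel()].
#' @param count_tbl Output of [relevance_counts_by_class()].
#' @return Tibble with class, channel, zcr, rel_count — one point per
#'   (channel, class).
#' @export
quadrant_points <- function(zcr_tbl, count_tbl) {
  dplyr::inner_join(zcr_tbl, count_tbl, by = c("class", "channel"))
}

#' Assign quadrants in ZCR-by-relevance space
#'
#' Splits (channel, class) points at the given thresholds (medians over
#' all points by default): Q1 = high relevance count and high ZCR, Q2 =
#' low relevance and high ZCR, Q3 = high relevance and low ZCR, Q4 = low
#' and low. "High" means strictly above the threshold, so points exactly
#' on a threshold fall to the low side.
#'
#' @param points Tibble with `zcr` and `rel_count` columns (see
#'   [quadrant_points()]).
#' @param zcr_threshold,count_threshold Numeric thresholds; default is the
#'   median of the respective column.
#' @return `points` with a `quadrant` factor column and attribute
#'   `thresholds`.
#' @export
quadrant_assign <- function(points, zcr_threshold = NULL, count_threshold = NULL) {
  if (nrow(points) == 0) abort("empty point set.")
  zt <- zcr_threshold %||% stats::median(points$zcr)
  ct <- count_threshold %||% stats::median(points$rel_count)
  high_r <- points$rel_count > ct
  high_z <- points$zcr > zt
  q <- dplyr::case_when(
    high_r & high_z ~ "Q1",
    !high_r & high_z ~ "Q2",
    high_r & !high_z ~ "Q3",
    .default = "Q4"
  )
  points$quadrant <- factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))
  attr(points, "thresholds") <- c(zcr = zt, count = ct)
  points
}

#' Per-class quadrant tallies
#'
#' @param points A [quadrant_assign()] result.
#' @return Tibble of counts per (class, quadrant), including zero cells.
#' @export
quadrant_tally <- function(points) {
  points %>%
    dplyr::count(.data$class, .data$quadrant, .drop = FALSE) %>%
    tidyr::complete(.data$class, .data$quadrant, fill = list(n = 0L))
}

#' Accumulated input relevance across classes
#'
#' Sums each channel's relevance share over all class columns,
#' re-normalizes to 1 and sorts descending — the "which sensors does the
#' model use overall" view.
#'
#' @param class_matrix A [classwise_mean_relevance()] matrix (columns sum
#'   to 1).
#' @return Tibble with channel and relevance, sorted descending.
#' @export
accumulated_input_relevance <- function(class_matrix) {
  totals <- rowSums(class_matrix)
  totals <- totals / sum(totals)
  tibble(
    channel = rownames(class_matrix) %||% paste0("u", seq_along(totals)),
    relevance = as.numeric(totals)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$relevance))
}

#' Class-conditional hidden-unit relevance matrix
#'
#' For each correctly classified sample, sums absolute hidden-unit
#' relevance over time and l1-normalizes it; the per-class averages form a
#' `nh x n_classes` matrix with unit column sums. Rows are sorted by the
#' `sort_class` column (descending), and the highlight set is the smallest
#' prefix of the all-class accumulated ranking whose cumulative share
#' exceeds `highlight_threshold`.
#'
#' @param maps List of `har_relevance` maps.
#' @param labels,predictions True and predicted class ids.
#' @param sort_class Class id whose column orders the rows (default: the
#'   first class).
#' @param highlight_threshold Cumulative-share threshold for the highlight
#'   set (default 0.55).
#' @return A `hidden_relevance` object: list with `values` (sorted
#'   matrix), `row_order` (permutation of unit indices), `highlight_set`
#'   (unit indices), `accumulated` (tibble of per-unit overall shares).
#' @export
hidden_relevance_matrix <- function(maps, labels, predictions,
                                    sort_class = NULL,
                                    highlight_threshold = 0.55) {
  v_list <- purrr::map(maps, function(m) {
    v <- colSums(abs(m$hidden_rel))
    stats::setNames(v, paste0("h", seq_along(v)))
  })
  values <- classwise_mean_relevance(v_list, labels, predictions)
  sort_class <- sort_class %||% as.integer(colnames(values)[1])
  col <- match(as.character(sort_class), colnames(values))
  if (is.na(col)) abort(sprintf("sort_class %s has no column.", sort_class))
  row_order <- order(values[, col], decreasing = TRUE)
  acc <- rowSums(values) / sum(values)
  rank <- order(acc, decreasing = TRUE)
  cum <- cumsum(acc[rank])
  n_high <- which(cum > highlight_threshold)[1]
  structure(
    list(
      values = values[row_order, , drop = FALSE],
      row_order = row_order,
      highlight_set = rank[seq_len(n_high)],
      accumulated = tibble(
        unit = rownames(values)[rank],
        share = as.numeric(acc[rank]),
        cumulative = as.numeric(cum)
      ),
      sort_class = sort_class,
      highlight_threshold = highlight_threshold
    ),
    class = "hidden_relevance"
  )
}

#' @export
print.hidden_relevance <- function(x, ...) {
  cat(sprintf(
    "<hidden_relevance> %d units x %d classes; %d units carry > %.0f%% of accumulated relevance\n",
    nrow(x$values), ncol(x$values), length(x$highlight_set),
    100 * x$highlight_threshold
  ))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
tidy.hidden_relevance <- function(x, ...) {
  as_tibble(x$values, rownames = "unit") %>%
    tidyr::pivot_longer(-"unit", names_to = "class", values_to = "relevance") %>%
    dplyr::mutate(class = as.integer(.data$class))
}
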