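#' Remove windows containing an all-zero sensor row
#'
#' A time row where all six channels are exactly zero marks a corrupted or
#' disconnected segment; any window containing at least one such row is
#' excluded in full so the window length stays fixed. A zero in a single
#' channel is not a trigger.
#'
#' @param data Long-format dataset tibble.
#' @return The retained windows, with attribute `excluded` holding the
#'   removed window ids (see [excluded_windows()]).
#' @export
filter_zero_rows <- function(data) {
  validate_har_data(data)
  if (nrow(data) == 0) abort("dataset is empty.")
  bad_rows <- dplyr::filter(data, dplyr::if_all(dplyr::all_of(har_channels()), ~ .x == 0))
  bad_ids <- unique(bad_rows$window_id)
  kept <- dplyr::filter(data, !.data$window_id %in% bad_ids)
  if (nrow(kept) == 0) {
    abort(c(
      "all windows contain zero rows; nothing retained.",
      i = paste0("excluded: ", paste(bad_ids, collapse = ", "))
    ))
  }
  kept <- set_har_attrs(kept,
    class_names = attr(data, "class_names"),
    provenance = attr(data, "provenance")
  )
  attr(kept, "excluded") <- bad_ids
  kept
}

#' Window ids excluded by the zero-row filter
#'
#' @param data Result of [filter_zero_rows()].
#' @return Character vector of excluded window ids.
#' @export
excluded_windows <- function(data) {
  attr(data, "excluded") %||% character()
}

#' Balance classes by truncation
#'
#' Truncates every class to the minimum per-class window count with a
#' seeded uniform draw of the retained windows; original window order is
#' preserved among those kept.
#'
#' @param data Long-format dataset tibble.
#' @param seed RNG seed for the per-class draws.
#' @return Balanced dataset tibble.
#' @export
balance_classes <- function(data, seed = 1) {
  validate_har_data(data)
  win <- dplyr::distinct(data, .data$window_id, .data$class)
  expected <- attr(data, "class_names")
  if (!is.null(expected)) {
    absent <- setdiff(as.integer(names(expected)), unique(win$class))
    if (length(absent) > 0) {
      abort(sprintf("class %s has zero windows.", paste(absent, collapse = ", ")))
    }
  }
  m <- min(table(win$class))
  keep <- withr::with_seed(seed, {
    win %>%
      dplyr::group_by(.data$class) %>%
      dplyr::group_map(~ sample(.x$window_id, m)) %>%
      unlist()
  })
  out <- dplyr::filter(data, .data$window_id %in% keep)
  set_har_attrs(out,
    class_names = attr(data, "class_names"),
    provenance = attr(data, "provenance")
  )
}

#' Stratified train/validation/test split
#'
#' Randomly partitions windows within each class: `floor(f1 * n)` to
#' training, `floor(f2 * n)` to validation and the remainder to test, so
#' the three partitions are disjoint and cover the input.
#'
#' @param data Balanced dataset tibble.
#' @param fractions Length-3 fractions summing to 1 (default 0.70 / 0.15 /
#'   0.15).
#' @param seed RNG seed for the within-class shuffles.
#' @return A `har_split` object: list with elements `train`, `val`, `test`
#'   (dataset tibbles), `split_seed` and `stats` (filled by
#'   [zscore_per_class()]).
#' @export
split_dataset <- function(data, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  validate_har_data(data)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three values summing to 1.")
  }
  win <- dplyr::distinct(data, .data$window_id, .data$class)
  parts <- list(train = character(), val = character(), test = character())
  withr::with_seed(seed, {
    for (k in sort(unique(win$class))) {
      ids <- win$window_id[win$class == k]
      ids <- sample(ids)
      n <- length(ids)
      n_tr <- floor(fractions[1] * n)
      n_va <- floor(fractions[2] * n)
      if (n_tr < 1 || n_va < 1 || n - n_tr - n_va < 1) {
        abort(sprintf("class %d has too few windows (%d) to fill all partitions.", k, n))
      }
      parts$train <- c(parts$train, ids[seq_len(n_tr)])
      parts$val <- c(parts$val, ids[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, ids[(n_tr + n_va + 1):n])
    }
  })
  take <- function(ids) {
    set_har_attrs(
      dplyr::filter(data, .data$window_id %in% ids),
      class_names = attr(data, "class_names"),
      provenance = attr(data, "provenance")
    )
  }
  structure(
    list(
      train = take(parts$train), val = take(parts$val), test = take(parts$test),
      split_seed = seed, stats = NULL
    ),
    class = "har_split"
  )
}

#' @export
print.har_split <- function(x, ...) {
  n <- function(d) length(unique(d$window_id))
  cat(sprintf(
    "<har_split> train %d / val %d / test %d windows (seed %s)%s\n",
    n(x$train), n(x$val), n(x$test), x$split_seed,
    if (is.null(x$stats)) "" else ", z-scored"
  ))
  invisible(x)
}

#' Per-class per-channel z-score normalization
#'
#' Standardizes every value to `(x - mu) / sigma`, where the mean and the
#' population standard deviation are computed per (class, channel) over all
#' data points of that class — by default over the full split (train, val
#' and test pooled), matching a normalization defined on whole-class data.
#' Set `train_only = TRUE` for a leakage-free variant where statistics come
#' from the training partition only.
#'
#' @param split A [split_dataset()] result.
#' @param train_only Compute statistics from the training partition only.
#' @return The split with all three partitions standardized and `stats` set
#'   to a tibble of (class, channel, mu, sigma).
#' @export
zscore_per_class <- function(split, train_only = FALSE) {
  if (!inherits(split, "har_split")) abort("`split` must be a har_split.")
  src <- if (train_only) split$train else dplyr::bind_rows(split$train, split$val, split$test)
  stats_tbl <- channel_stats(src)
  degenerate <- dplyr::filter(stats_tbl, .data$sigma <= 0)
  if (nrow(degenerate) > 0) {
    abort(sprintf(
      "degenerate (constant) channel: class %d, channel %s has zero variance.",
      degenerate$class[1], degenerate$channel[1]
    ))
  }
  split$train <- zscore_apply(split$train, stats_tbl)
  split$val <- zscore_apply(split$val, stats_tbl)
  split$test <- zscore_apply(split$test, stats_tbl)
  split$stats <- stats_tbl
  split
}

#' Per-(class, channel) mean and population standard deviation
#'
#' @param data Long-format dataset tibble.
#' @return Tibble with columns class, channel, mu, sigma.
#' @export
channel_stats <- function(data) {
  validate_har_data(data)
  data %>%
    tidyr::pivot_longer(dplyr::all_of(har_channels()),
      names_to = "channel", values_to = "x"
    ) %>%
    dplyr::group_by(.data$class, .data$channel) %>%
    dplyr::summarise(
      mu = mean(.data$x),
      sigma = sqrt(mean((.data$x - mean(.data$x))^2)),
      .groups = "drop"
    )
}

#' Apply or invert per-class channel statistics
#'
#' `zscore_apply()` standardizes a dataset with precomputed statistics;
#' `zscore_invert()` maps standardized values back to sensor units, making
#' the transform auditable (round-trip error is at floating-point level).
#'
#' @param data Long-format dataset tibble.
#' @param stats_tbl Statistics tibble from [channel_stats()].
#' @return Transformed dataset tibble.
#' @export
zscore_apply <- function(data, stats_tbl) {
  transform_channels(data, stats_tbl, function(x, mu, sigma) (x - mu) / sigma)
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(data, stats_tbl) {
  transform_channels(data, stats_tbl, function(x, mu, sigma) x * sigma + mu)
}

transform_channels <- function(data, stats_tbl, f) {
  validate_har_data(data)
  out <- data
  for (ch in har_channels()) {
    st <- stats_tbl[stats_tbl$channel == ch, ]
    mu <- stats::setNames(st$mu, st$class)
    sg <- stats::setNames(st$sigma, st$class)
    key <- as.character(out$class)
    out[[ch]] <- f(out[[ch]], unname(mu[key]), unname(sg[key]))
  }
  set_har_attrs(out,
    class_names = attr(data, "class_names"),
    provenance = attr(data, "provenance")
  )
}

#' @export
tidy.har_split <- function(x, ...) {
  purrr::imap(
    list(train = x$train, val = x$val, test = x$test),
    ~ dplyr::distinct(.x, .data$window_id, .data$class) %>%
      dplyr::count(.data$class) %>%
      dplyr::mutate(partition = .y)
  ) %>%
    dplyr::bind_rows() %>%
    dplyr::select("partition", "class", "n")
}
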