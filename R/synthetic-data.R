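#' Describe one activity class for the signal simulator
#'
#' An activity class is modelled as a quasi-periodic motion: every sensor
#' channel carries the same fundamental frequency (with optional harmonics)
#' at a channel-specific amplitude and phase, on top of which i.i.d.
#' Gaussian noise is added per window. Distinct fundamentals across classes
#' are what makes classes separable from raw signals.
#'
#' @param class_id Positive integer identifier; classes in a dataset must be
#'   numbered 1..K consecutively.
#' @param name Human-readable label.
#' @param fundamental_hz Frequency (Hz) of the dominant periodic component;
#'   must be positive and, together with the highest harmonic, below the
#'   Nyquist frequency of the generator.
#' @param channel_amplitudes Numeric vector of length 6 (order
#'   [har_channels()]), all non-negative, at least one positive. Sensor
#'   units.
#' @param channel_phases Numeric vector of length 6, radians.
#' @param harmonic_weights Relative amplitudes of harmonics 1..K of the
#'   fundamental.
#'
#' @return An object of class `har_class_spec`.
#' @export
#' @examples
#' har_class_spec(1, "walk-like", 2, channel_amplitudes = c(1, .3, 1, .8, .9, .6))
har_class_spec <- function(class_id, name, fundamental_hz,
                           channel_amplitudes,
                           channel_phases = rep(pi / 4, 6),
                           harmonic_weights = 1) {
  if (length(class_id) != 1L || class_id < 1 || class_id != round(class_id)) {
    abort("`class_id` must be a single positive integer.")
  }
  if (!is.numeric(fundamental_hz) || fundamental_hz <= 0) {
    abort("`fundamental_hz` must be positive.")
  }
  if (length(channel_amplitudes) != 6L || any(channel_amplitudes < 0)) {
    abort("`channel_amplitudes` must be 6 non-negative values.")
  }
  if (!any(channel_amplitudes > 0)) {
    abort("at least one channel amplitude must be positive.")
  }
  if (length(channel_phases) != 6L) {
    abort("`channel_phases` must have length 6.")
  }
  structure(
    list(
      class_id = as.integer(class_id), name = as.character(name),
      fundamental_hz = fundamental_hz,
      channel_amplitudes = as.numeric(channel_amplitudes),
      channel_phases = as.numeric(channel_phases),
      harmonic_weights = as.numeric(harmonic_weights)
    ),
    class = "har_class_spec"
  )
}

#' Default three-activity class specifications
#'
#' Three classes emulating slow trunk flexion ("sit-up-like", 0.5 Hz), gait
#' ("walk-like", 2 Hz) and stair ascent ("stairs-like", 1.5 Hz), with the
#' gyroscope y axis given the strongest between-class contrast and the
#' accelerometer y axis the weakest.
#'
#' @return A list of three [har_class_spec()] objects.
#' @export
default_class_specs <- function() {
  phases <- seq(0.3, by = 0.9, length.out = 6)
  list(
    har_class_spec(1, "sit-up", 0.5,
      channel_amplitudes = c(0.6, 0.2, 0.8, 0.5, 1.2, 0.4),
      channel_phases = phases,
      harmonic_weights = c(1, 0.5, 0.25)
    ),
    har_class_spec(2, "walk", 2,
      channel_amplitudes = c(1.0, 0.3, 1.1, 0.9, 0.8, 0.6),
      channel_phases = phases + 0.4,
      harmonic_weights = c(1, 0.3)
    ),
    har_class_spec(3, "stairs", 1.5,
      channel_amplitudes = c(0.9, 0.35, 1.2, 0.7, 1.0, 0.5),
      channel_phases = phases + 0.8,
      harmonic_weights = c(1, 0.35, 0.15)
    )
  )
}

#' Class specifications with a single planted informative channel
#'
#' Builds class specs in which exactly one sensor channel carries
#' class-discriminative signal (distinct fundamentals per class) while all
#' other channels have zero deterministic amplitude, i.e. are pure noise and
#' identically distributed across classes. Used for ground-truth recovery
#' tests of attribution methods: any relevance method that works should rank
#' the planted channel first.
#'
#' @param channel Planted channel, as a name from [har_channels()] or an
#'   index 1..6. Default `"gyr_y"`.
#' @param fundamentals Per-class fundamentals (Hz), length defines the
#'   number of classes.
#' @param amplitude Signal amplitude on the planted channel.
#' @return A list of [har_class_spec()] objects.
#' @export
planted_class_specs <- function(channel = "gyr_y",
                                fundamentals = c(0.5, 2, 1.5),
                                amplitude = 1) {
  ch <- if (is.character(channel)) match(channel, har_channels()) else as.integer(channel)
  if (is.na(ch) || ch < 1 || ch > 6) abort("unknown `channel`.")
  harmonics <- list(c(1, 0.5), c(1, 0.3), c(1, 0.4))
  purrr::map(seq_along(fundamentals), function(k) {
    amps <- rep(0, 6)
    amps[ch] <- amplitude
    har_class_spec(
      k, paste0("class_", k), fundamentals[k],
      channel_amplitudes = amps,
      channel_phases = rep(pi / 4, 6),
      harmonic_weights = harmonics[[1 + (k - 1) %% length(harmonics)]]
    )
  })
}

#' Configuration of the synthetic-window generator
#'
#' @param fs Sampling rate in Hz (default 100).
#' @param window_s Window duration in seconds (default 3); `fs * window_s`
#'   must be a whole number of samples.
#' @param n_per_class Windows generated per class.
#' @param class_specs List of [har_class_spec()] objects with consecutive
#'   `class_id` 1..K.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   sensor units (default 0.5, a moderate noise level relative to the unit
#'   default amplitudes).
#' @param zero_row_fraction Fraction of windows corrupted with an all-zero
#'   time row, emulating sensor dropouts (default 0).
#' @param seed RNG seed making generation fully reproducible.
#' @return An object of class `har_generator_config`.
#' @export
har_generator_config <- function(n_per_class,
                                 class_specs = default_class_specs(),
                                 fs = 100, window_s = 3,
                                 noise_sd = 0.5, zero_row_fraction = 0,
                                 seed = 1) {
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive.")
  nt <- fs * window_s
  if (abs(nt - round(nt)) > 1e-9) abort("`fs * window_s` must be an integer.")
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
  if (length(class_specs) == 0) abort("`class_specs` must be non-empty.")
  if (zero_row_fraction < 0 || zero_row_fraction > 1) {
    abort("`zero_row_fraction` must be in [0, 1].")
  }
  ids <- map_int(class_specs, "class_id")
  if (!identical(sort(ids), seq_along(ids))) {
    abort("class specs must have consecutive class_id 1..K.")
  }
  for (spec in class_specs) {
    f_max <- spec$fundamental_hz * length(spec$harmonic_weights)
    if (f_max >= fs / 2) {
      abort(sprintf(
        "class %d: highest harmonic (%.2f Hz) is at or above Nyquist (%.2f Hz).",
        spec$class_id, f_max, fs / 2
      ))
    }
  }
  structure(
    list(
      fs = fs, window_s = window_s, n_t = as.integer(round(nt)),
      n_per_class = as.integer(n_per_class), class_specs = class_specs,
      noise_sd = noise_sd, zero_row_fraction = zero_row_fraction,
      seed = as.integer(seed)
    ),
    class = "har_generator_config"
  )
}

# Deterministic noiseless waveform of one class: NT x 6 matrix.
class_signal_matrix <- function(spec, fs, n_t) {
  t <- (seq_len(n_t) - 1) / fs
  out <- matrix(0, n_t, 6, dimnames = list(NULL, har_channels()))
  for (ch in 1:6) {
    if (spec$channel_amplitudes[ch] == 0) next
    s <- 0
    for (k in seq_along(spec$harmonic_weights)) {
      s <- s + spec$harmonic_weights[k] *
        sin(2 * pi * k * spec$fundamental_hz * t + spec$channel_phases[ch])
    }
    out[, ch] <- spec$channel_amplitudes[ch] * s
  }
  out
}

#' Generate a labeled synthetic inertial dataset
#'
#' Produces `n_per_class * K` windows of `fs * window_s` samples times 6
#' channels in long format. Each window is the deterministic class waveform
#' (sum of harmonics of the class fundamental) plus i.i.d. Gaussian noise.
#' Identical config (including seed) gives bit-identical output.
#'
#' @param config A [har_generator_config()].
#' @return A tibble with columns `window_id`, `class`, `t_index` and the six
#'   channel columns of [har_channels()]; attributes `class_names`
#'   (id-to-name map) and `provenance` (config hash + seed).
#' @export
#' @examples
#' d <- generate_dataset(har_generator_config(n_per_class = 2, seed = 1))
#' dplyr::count(d, class)
generate_dataset <- function(config) {
  if (!inherits(config, "har_generator_config")) {
    abort("`config` must be a har_generator_config.")
  }
  n_t <- config$n_t
  base <- purrr::map(config$class_specs, class_signal_matrix,
    fs = config$fs, n_t = n_t
  )
  n_cl <- length(config$class_specs)
  n_win <- config$n_per_class * n_cl
  wid <- 0L
  pieces <- vector("list", n_win)
  withr::with_seed(config$seed, {
    for (k in seq_len(n_cl)) {
      for (r in seq_len(config$n_per_class)) {
        wid <- wid + 1L
        vals <- base[[k]]
        if (config$noise_sd > 0) {
          vals <- vals + matrix(rnorm(n_t * 6, 0, config$noise_sd), n_t, 6)
        }
        colnames(vals) <- har_channels()
        pieces[[wid]] <- dplyr::bind_cols(
          tibble(
            window_id = sprintf("w%05d", wid),
            class = config$class_specs[[k]]$class_id,
            t_index = seq_len(n_t)
          ),
          as_tibble(vals)
        )
      }
    }
  })
  out <- dplyr::bind_rows(pieces)
  class_names <- stats::setNames(
    map_chr(config$class_specs, "name"),
    map_int(config$class_specs, "class_id")
  )
  out <- set_har_attrs(out,
    class_names = class_names,
    provenance = list(config_hash = hash(config), seed = config$seed)
  )
  if (config$zero_row_fraction > 0) {
    out <- inject_zero_rows(out, config$zero_row_fraction,
      seed = config$seed + 1L
    )
  }
  out
}

#' @importFrom purrr map_chr
set_har_attrs <- function(data, class_names = NULL, provenance = NULL) {
  if (!is.null(class_names)) attr(data, "class_names") <- class_names
  if (!is.null(provenance)) attr(data, "provenance") <- provenance
  data
}

#' Corrupt a fraction of windows with all-zero sensor rows
#'
#' Selects `floor(fraction * N)` windows without replacement and sets one
#' randomly chosen time row to exact zero across all six channels,
#' emulating the disconnected-sensor rows that preprocessing must detect
#' and remove.
#'
#' @param data A long-format dataset as from [generate_dataset()].
#' @param fraction Proportion of windows to corrupt, in [0, 1].
#' @param seed RNG seed for the window and row draws.
#' @return The dataset with corrupted rows; attribute `zero_rows` records a
#'   tibble of (window_id, t_index) that were zeroed.
#' @export
inject_zero_rows <- function(data, fraction, seed = 1) {
  validate_har_data(data)
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  ids <- unique(data$window_id)
  k <- floor(fraction * length(ids))
  if (k == 0) {
    attr(data, "zero_rows") <- tibble(window_id = character(), t_index = integer())
    return(data)
  }
  n_t <- max(data$t_index)
  withr::with_seed(seed, {
    chosen <- sample(ids, k)
    rows <- sample.int(n_t, k, replace = TRUE)
  })
  plan <- tibble(window_id = chosen, t_index = rows)
  hit <- paste(data$window_id, data$t_index) %in% paste(plan$window_id, plan$t_index)
  data[hit, har_channels()] <- 0
  attr(data, "zero_rows") <- plan
  data
}

# Shared column validation for long-format datasets.
validate_har_data <- function(data) {
  needed <- c("window_id", "class", "t_index", har_channels())
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing columns: ", paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Class id to name map of a dataset
#'
#' @param data A dataset tibble.
#' @return Named character vector (names are class ids), falling back to
#'   `class_<id>` labels when no map is attached.
#' @export
class_names <- function(data) {
  cn <- attr(data, "class_names")
  ids <- sort(unique(data$class))
  if (is.null(cn)) {
    return(stats::setNames(paste0("class_", ids), ids))
  }
  cn[as.character(ids)]
}

#' Read/write datasets as long-format CSV
#'
#' The on-disk schema is one row per (window, time step):
#' `window_id, class, t_index, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`.
#'
#' @param data Dataset tibble.
#' @param path File path.
#' @return `write_har_csv()` returns `data` invisibly; `read_har_csv()`
#'   returns the dataset tibble.
#' @export
write_har_csv <- function(data, path) {
  validate_har_data(data)
  readr::write_csv(data[, c("window_id", "class", "t_index", har_channels())], path)
  invisible(data)
}

#' @rdname write_har_csv
#' @export
read_har_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  data$class <- as.integer(data$class)
  data$t_index <- as.integer(data$t_index)
  validate_har_data(data)
  data
}

#' Write or read a generator configuration as YAML
#'
#' @param config A [har_generator_config()].
#' @param path File path.
#' @export
write_generator_config <- function(config, path) {
  spec_list <- purrr::map(config$class_specs, function(s) {
    list(
      class_id = s$class_id, name = s$name,
      fundamental_hz = s$fundamental_hz,
      channel_amplitudes = s$channel_amplitudes,
      channel_phases = s$channel_phases,
      harmonic_weights = s$harmonic_weights
    )
  })
  yaml::write_yaml(
    list(
      fs = config$fs, window_s = config$window_s,
      n_per_class = config$n_per_class, noise_sd = config$noise_sd,
      zero_row_fraction = config$zero_row_fraction, seed = config$seed,
      class_specs = spec_list
    ),
    path
  )
  invisible(config)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- purrr::map(raw$class_specs, function(s) {
    har_class_spec(
      s$class_id, s$name, s$fundamental_hz,
      channel_amplitudes = unlist(s$channel_amplitudes),
      channel_phases = unlist(s$channel_phases),
      harmonic_weights = unlist(s$harmonic_weights)
    )
  })
  har_generator_config(
    n_per_class = raw$n_per_class, class_specs = specs,
    fs = raw$fs, window_s = raw$window_s, noise_sd = raw$noise_sd,
    zero_row_fraction = raw$zero_row_fraction %||% 0, seed = raw$seed %||% 1
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
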