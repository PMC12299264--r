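#' End-to-end experiment configuration
#'
#' Bundles the stage configurations of a full run: generation,
#' preprocessing, the training grid, relevance propagation and the
#' downstream analytics. All stage seeds are derived from `seed` unless a
#' stage sets its own.
#'
#' @param generator A [har_generator_config()].
#' @param grid A [grid_spec()].
#' @param training A [train_config()].
#' @param lrp An [lrp_config()].
#' @param fractions Train/val/test fractions (default 0.70/0.15/0.15).
#' @param train_only_stats Use training-partition-only normalization
#'   statistics (default FALSE: per-class statistics over the full data).
#' @param quantile Top-relevance threshold quantile for the counting
#'   analytics (default 0.70).
#' @param highlight_threshold Cumulative hidden-relevance highlight
#'   threshold (default 0.55).
#' @param out_dir Output directory; created if missing.
#' @param seed Global seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator, grid,
                              training = train_config(),
                              lrp = lrp_config(),
                              fractions = c(0.70, 0.15, 0.15),
                              train_only_stats = FALSE,
                              quantile = 0.70,
                              highlight_threshold = 0.55,
                              out_dir = tempfile("har_run_"),
                              seed = 1) {
  if (!inherits(generator, "har_generator_config")) abort("`generator` must be a har_generator_config.")
  if (!inherits(grid, "grid_spec")) abort("`grid` must be a grid_spec.")
  if (!inherits(training, "train_config")) abort("`training` must be a train_config.")
  if (!inherits(lrp, "lrp_config")) abort("`lrp` must be an lrp_config.")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three values summing to 1.")
  }
  structure(
    list(
      generator = generator, grid = grid, training = training, lrp = lrp,
      fractions = fractions, train_only_stats = isTRUE(train_only_stats),
      quantile = quantile, highlight_threshold = highlight_threshold,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Load and validate an experiment configuration from YAML
#'
#' Reads a YAML file describing the generator, grid, training and LRP
#' settings, fills documented defaults for anything omitted, and runs the
#' full invariant checks of [experiment_config()].
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  gen_raw <- raw$generator %||% abort("config must contain a `generator` block.")
  specs <- if (is.null(gen_raw$class_specs)) {
    default_class_specs()
  } else {
    purrr::map(gen_raw$class_specs, function(s) {
      har_class_spec(
        s$class_id, s$name %||% paste0("class_", s$class_id),
        s$fundamental_hz,
        channel_amplitudes = unlist(s$channel_amplitudes),
        channel_phases = unlist(s$channel_phases %||% rep(pi / 4, 6)),
        harmonic_weights = unlist(s$harmonic_weights %||% 1)
      )
    })
  }
  generator <- har_generator_config(
    n_per_class = gen_raw$n_per_class %||% abort("generator.n_per_class is required."),
    class_specs = specs,
    fs = gen_raw$fs %||% 100, window_s = gen_raw$window_s %||% 3,
    noise_sd = gen_raw$noise_sd %||% 0.5,
    zero_row_fraction = gen_raw$zero_row_fraction %||% 0,
    seed = gen_raw$seed %||% raw$seed %||% 1
  )
  g <- raw$grid %||% list()
  grid <- grid_spec(
    architectures = unlist(g$architectures %||% c("firnn", "lstm", "gru")),
    delays = unlist(g$delays %||% c(1, seq(10, 100, by = 10))),
    hidden_sizes = unlist(g$hidden_sizes %||% c(2, 4, 6, 8, 10)),
    repetitions = g$repetitions %||% 100,
    base_seed = g$base_seed %||% raw$seed %||% 1
  )
  tr <- raw$training %||% list()
  training <- train_config(
    learning_rate = tr$learning_rate %||% 1e-3,
    max_epochs = tr$max_epochs %||% 200,
    patience = tr$patience %||% 10,
    batch_size = tr$batch_size %||% 32,
    seed = tr$seed %||% raw$seed %||% 1
  )
  l <- raw$lrp %||% list()
  lrp <- lrp_config(
    epsilon = l$epsilon %||% 1e-6,
    gate_policy = l$gate_policy %||% "signal-takes-all"
  )
  experiment_config(
    generator = generator, grid = grid, training = training, lrp = lrp,
    fractions = unlist(raw$fractions %||% c(0.70, 0.15, 0.15)),
    train_only_stats = raw$train_only_stats %||% FALSE,
    quantile = raw$quantile %||% 0.70,
    highlight_threshold = raw$highlight_threshold %||% 0.55,
    out_dir = raw$out_dir %||% tempfile("har_run_"),
    seed = raw$seed %||% 1
  )
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(x, path)
  path
}

#' Run the full experiment pipeline
#'
#' Executes generate, preprocess (zero-row filter, class balancing,
#' stratified split, per-class z-score), grid training, best-model
#' selection, complexity accounting, relevance propagation on the test
#' partition and the downstream analytics, writing every stage output plus
#' a manifest (config hash, seeds, content hashes) to `config$out_dir`.
#' Re-running the same configuration reproduces every output exactly.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list with the split, results table, best records,
#'   models, confusion matrices, analytics tables and the manifest.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) abort("`config` must be an experiment_config.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stage <- function(name, expr) {
    inform(sprintf("[%s] ...", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
    })
  }

  data <- stage("generate", generate_dataset(config$generator))
  files <- c(files, write_stage_csv(data, config$out_dir, "data.csv"))

  split <- stage("preprocess", {
    filtered <- filter_zero_rows(data)
    jsonlite::write_json(
      list(excluded = excluded_windows(filtered)),
      file.path(config$out_dir, "exclusions.json")
    )
    balanced <- balance_classes(filtered, seed = config$seed)
    sp <- split_dataset(balanced, fractions = config$fractions, seed = config$seed)
    zscore_per_class(sp, train_only = config$train_only_stats)
  })
  files <- c(
    files, file.path(config$out_dir, "exclusions.json"),
    write_stage_csv(split$stats, config$out_dir, "channel_stats.csv")
  )

  results <- stage("grid", run_grid(split, config$grid, config$training))
  files <- c(files, write_stage_csv(results, config$out_dir, "results.csv"))

  best <- stage("select", {
    purrr::map(config$grid$architectures, ~ select_best(results, .x)) %>%
      dplyr::bind_rows()
  })
  files <- c(files, write_stage_csv(best, config$out_dir, "best_models.csv"))

  cx <- stage("complexity", {
    dims_list <- purrr::map(
      seq_len(nrow(best)),
      ~ arch_dims(best$nd[.x], best$nh[.x], ni = best$ni[.x], nc = best$nc[.x])
    )
    complexity_table(best$arch, dims_list)
  })
  files <- c(files, write_stage_csv(cx, config$out_dir, "complexity.csv"))

  models <- stage("refit", {
    out <- purrr::map(
      seq_len(nrow(best)),
      ~ refit_run(split, best[.x, ], config$training)
    )
    stats::setNames(out, best$arch)
  })

  analysis <- stage("explain", {
    purrr::map(models, function(model) {
      lr <- lrp_dataset(model, split$test, config$lrp)
      v_list <- purrr::map(lr$maps, normalize_global, layer = "input")
      classwise <- classwise_mean_relevance(
        v_list, lr$predictions$truth, lr$predictions$predicted
      )
      points <- quadrant_assign(quadrant_points(
        zcr_by_class_channel(split$test, fs = config$generator$fs),
        relevance_counts_by_class(
          lr$maps, lr$predictions$truth, lr$predictions$predicted,
          quantile = config$quantile
        )
      ))
      hidden <- hidden_relevance_matrix(
        lr$maps, lr$predictions$truth, lr$predictions$predicted,
        highlight_threshold = config$highlight_threshold
      )
      list(
        lrp = lr, classwise = classwise,
        accumulated = accumulated_input_relevance(classwise),
        points = points, tally = quadrant_tally(points), hidden = hidden,
        confusion = confusion_matrix(model, split$test)
      )
    })
  })
  for (arch in names(analysis)) {
    a <- analysis[[arch]]
    files <- c(
      files,
      write_stage_csv(
        as_tibble(a$classwise, rownames = "channel"),
        config$out_dir, sprintf("classwise_relevance_%s.csv", arch)
      ),
      write_stage_csv(a$accumulated, config$out_dir, sprintf("global_relevance_%s.csv", arch)),
      write_stage_csv(a$points, config$out_dir, sprintf("quadrants_%s.csv", arch)),
      write_stage_csv(
        as_tibble(a$hidden$values, rownames = "unit"),
        config$out_dir, sprintf("hidden_relevance_%s.csv", arch)
      )
    )
  }

  manifest <- list(
    config_hash = hash(config),
    seed = config$seed,
    files = purrr::map(
      stats::setNames(files, basename(files)),
      ~ hash(readLines(.x, warn = FALSE))
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(list(
    data = data, split = split, results = results, best = best,
    models = models, analysis = analysis, manifest = manifest,
    out_dir = config$out_dir
  ))
}
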