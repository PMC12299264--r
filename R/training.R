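#' Training configuration
#'
#' Categorical cross-entropy minimized with Adam. Early stopping monitors
#' validation accuracy: training stops when it has not improved for
#' `patience` consecutive epochs, and the parameters with the best
#' validation accuracy seen are returned.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs Maximum epochs (default 200).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batch_size Minibatch size (default 32); sets of at most 64
#'   training windows are trained full-batch.
#' @param weight_decay Decoupled L2 penalty applied at each Adam step
#'   (default 0). Useful against overfitting when the parameter count
#'   rivals the number of training windows.
#' @param seed RNG seed for initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 200,
                         patience = 10, batch_size = 32,
                         weight_decay = 0, seed = 1) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (weight_decay < 0) abort("`weight_decay` must be non-negative.")
  if (max_epochs < 1 || patience < 1 || batch_size < 1) {
    abort("`max_epochs`, `patience` and `batch_size` must be positive.")
  }
  structure(
    list(
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), batch_size = as.integer(batch_size),
      weight_decay = weight_decay, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_update <- function(state, theta, grad, lr, weight_decay = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  m_hat <- state$m / (1 - beta1^state$t)
  v_hat <- state$v / (1 - beta2^state$t)
  theta_new <- theta - lr * (m_hat / (sqrt(v_hat) + eps) + weight_decay * theta)
  list(state = state, theta = theta_new)
}

split_arrays <- function(split, nd) {
  take <- function(d) {
    w <- as_window_array(d)
    list(X = suffix_array(w$X, nd), y = w$labels, ids = w$ids)
  }
  list(train = take(split$train), val = take(split$val), test = take(split$test))
}

accuracy_of <- function(params, part) {
  mean(predict_batch(params, part$X) == part$y)
}

# Accuracy and mean cross-entropy in one forward pass.
eval_part <- function(params, part) {
  fwd <- net_forward(params, part$X)
  pred <- max.col(fwd$probs, ties.method = "first")
  p_true <- fwd$probs[cbind(seq_along(part$y), part$y)]
  list(acc = mean(pred == part$y), loss = -mean(log(pmax(p_true, 1e-300))))
}

#' Train one network on a preprocessed split
#'
#' Minimizes categorical cross-entropy by backpropagation (through the FIR
#' taps for the FIRNN, through time for LSTM/GRU) with Adam, early-stopping
#' on validation accuracy and restoring the best-validation parameters.
#' Identical inputs and seeds reproduce the run exactly.
#'
#' @param split A z-scored [split_dataset()] result.
#' @param arch One of `"firnn"`, `"lstm"`, `"gru"`.
#' @param dims An [arch_dims()].
#' @param config A [train_config()].
#' @param on_divergence `"error"` aborts on a non-finite loss; `"flag"`
#'   records the run as diverged instead.
#' @return A `har_model`: list with `params`, `arch`, `dims`, `record` (a
#'   one-row tibble of accuracies and metadata) and `history` (per-epoch
#'   loss and validation accuracy).
#' @export
train_model <- function(split, arch, dims, config = train_config(),
                        on_divergence = c("error", "flag"),
                        hidden_activation = c("sigmoid", "tanh")) {
  arch <- match.arg(arch, har_architectures)
  on_divergence <- match.arg(on_divergence)
  if (!inherits(split, "har_split")) abort("`split` must be a har_split.")
  arr <- split_arrays(split, dims$nd)
  n_tr <- length(arr$train$y)
  params <- init_params(arch, dims,
    seed = config$seed,
    hidden_activation = match.arg(hidden_activation)
  )
  theta <- flatten_params(params)
  state <- adam_init(length(theta))
  bs <- if (n_tr <= 64) n_tr else min(config$batch_size, n_tr)
  best <- list(theta = theta, val = -Inf, val_loss = Inf, epoch = 0L)
  wait <- 0L
  diverged <- FALSE
  history <- vector("list", config$max_epochs)
  epoch <- 0L
  if (config$learning_rate > 0) {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- withr::with_seed(config$seed + epoch, sample.int(n_tr))
      ep_loss <- 0
      for (b in seq_len(ceiling(n_tr / bs))) {
        idx <- ord[((b - 1) * bs + 1):min(b * bs, n_tr)]
        cur <- unflatten_params(theta, params)
        lg <- loss_and_grads(cur, arr$train$X[idx, , , drop = FALSE], arr$train$y[idx])
        if (!is.finite(lg$loss)) {
          diverged <- TRUE
          break
        }
        ep_loss <- ep_loss + lg$loss * length(idx)
        upd <- adam_update(state, theta, flatten_params(lg$grads),
          config$learning_rate, config$weight_decay
        )
        state <- upd$state
        theta <- upd$theta
      }
      if (diverged) {
        if (on_divergence == "error") {
          abort(sprintf("training diverged (non-finite loss): %s, seed %d.", arch, config$seed))
        }
        break
      }
      ev <- eval_part(unflatten_params(theta, params), arr$val)
      history[[epoch]] <- tibble(
        epoch = epoch, loss = ep_loss / n_tr,
        val_acc = ev$acc, val_loss = ev$loss
      )
      # checkpoint on best validation accuracy; equal accuracy keeps the
      # better-margin (lower validation loss) parameters
      if (ev$acc > best$val || (ev$acc == best$val && ev$loss < best$val_loss)) {
        best <- list(theta = theta, val = ev$acc, val_loss = ev$loss, epoch = epoch)
      }
      if (best$epoch == epoch) {
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }
  final <- unflatten_params(best$theta, params)
  record <- tibble(
    arch = arch, ni = dims$ni, nd = dims$nd, nh = dims$nh, nc = dims$nc,
    seed = config$seed,
    train_acc = accuracy_of(final, arr$train),
    val_acc = accuracy_of(final, arr$val),
    test_acc = accuracy_of(final, arr$test),
    epochs = epoch, n_params = n_params(final),
    checksum = hash(final), diverged = diverged
  )
  structure(
    list(
      params = final, arch = arch, dims = dims, record = record,
      history = dplyr::bind_rows(history)
    ),
    class = "har_model"
  )
}

#' @export
print.har_model <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "<har_model> %s (ni=%d, nd=%d, nh=%d, nc=%d): train %.3f / val %.3f / test %.3f (%d epochs)\n",
    r$arch, r$ni, r$nd, r$nh, r$nc, r$train_acc, r$val_acc, r$test_acc, r$epochs
  ))
  invisible(x)
}

#' @export
glance.har_model <- function(x, ...) x$record

#' @export
tidy.har_model <- function(x, ...) {
  purrr::imap(unclass(x$params), function(v, nm) {
    tibble(
      term = nm,
      shape = paste(dim(v) %||% length(v), collapse = "x"),
      n = length(v),
      l2_norm = sqrt(sum(v^2))
    )
  }) %>% dplyr::bind_rows()
}

#' Factorial experiment grid
#'
#' @param architectures Subset of `c("firnn", "lstm", "gru")`.
#' @param delays Ordered delay values; the default is the 11-point grid 1
#'   then 10 to 100 in steps of 10.
#' @param hidden_sizes Ordered hidden-layer sizes (default 2, 4, 6, 8, 10).
#' @param repetitions Independent repetitions per cell (default 100).
#' @param base_seed Seed from which each run's seed is derived.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(architectures = c("firnn", "lstm", "gru"),
                      delays = c(1, seq(10, 100, by = 10)),
                      hidden_sizes = c(2, 4, 6, 8, 10),
                      repetitions = 100, base_seed = 1) {
  architectures <- match.arg(architectures, har_architectures, several.ok = TRUE)
  if (length(delays) == 0 || length(hidden_sizes) == 0 || repetitions < 1) {
    abort("grid axes must be non-empty and `repetitions` >= 1.")
  }
  structure(
    list(
      architectures = architectures, delays = as.integer(delays),
      hidden_sizes = as.integer(hidden_sizes),
      repetitions = as.integer(repetitions), base_seed = as.integer(base_seed)
    ),
    class = "grid_spec"
  )
}

# Reproducible per-run seed, collision-resistant across the grid and
# always below 2^31.
derive_seed <- function(base_seed, arch, nd, nh, repetition) {
  key <- paste(base_seed, arch, nd, nh, repetition, sep = "/")
  strtoi(substr(hash(key), 1, 7), 16L)
}

#' Enumerate a grid without training
#'
#' One row per (architecture x delay x hidden size x repetition) with its
#' derived run seed; the row count is the product of the axis lengths.
#'
#' @param spec A [grid_spec()].
#' @return Tibble with columns arch, nd, nh, repetition, seed.
#' @export
grid_plan <- function(spec) {
  if (!inherits(spec, "grid_spec")) abort("`spec` must be a grid_spec.")
  plan <- tidyr::expand_grid(
    arch = spec$architectures, nd = spec$delays,
    nh = spec$hidden_sizes, repetition = seq_len(spec$repetitions)
  )
  plan$seed <- purrr::pmap_int(
    plan,
    function(arch, nd, nh, repetition) {
      derive_seed(spec$base_seed, arch, nd, nh, repetition)
    }
  )
  plan
}

#' Run a factorial training grid
#'
#' Trains one model per grid row. Divergent runs are flagged in the
#' results table rather than aborting, so the row count always equals the
#' grid cardinality.
#'
#' @param split A z-scored [split_dataset()] result.
#' @param spec A [grid_spec()].
#' @param config A [train_config()]; its seed is replaced per run by the
#'   grid-derived seed.
#' @param ni,nc Input/output dimensions (defaults 6 and the number of
#'   classes in the split).
#' @return Tibble of run records, one per grid row.
#' @export
run_grid <- function(split, spec, config = train_config(),
                     ni = 6, nc = length(unique(split$train$class))) {
  plan <- grid_plan(spec)
  records <- purrr::pmap(plan, function(arch, nd, nh, repetition, seed) {
    cfg <- config
    cfg$seed <- seed
    model <- train_model(split, arch, arch_dims(nd, nh, ni = ni, nc = nc),
      config = cfg, on_divergence = "flag"
    )
    dplyr::mutate(model$record, repetition = repetition)
  })
  dplyr::bind_rows(records) %>%
    dplyr::select("arch", "nd", "nh", "repetition", dplyr::everything())
}

#' Select the best run of an architecture
#'
#' Maximizes validation accuracy; ties break to the smaller parameter
#' count, then the lower seed.
#'
#' @param results A [run_grid()] results tibble.
#' @param arch Architecture to select within.
#' @return The winning one-row record.
#' @export
select_best <- function(results, arch) {
  sub <- dplyr::filter(results, .data$arch == !!arch, !.data$diverged)
  if (nrow(sub) == 0) abort(sprintf("no (non-diverged) records for '%s'.", arch))
  sub %>%
    dplyr::arrange(dplyr::desc(.data$val_acc), .data$n_params, .data$seed) %>%
    dplyr::slice(1)
}

#' Re-train the model behind a grid record
#'
#' Grid results store metadata only; because run seeds fully determine a
#' run, the trained parameters are recovered by re-running that record.
#'
#' @param split The same split the grid used.
#' @param record One row of a [run_grid()] result.
#' @param config The same [train_config()] the grid used.
#' @return A `har_model`.
#' @export
refit_run <- function(split, record, config = train_config()) {
  cfg <- config
  cfg$seed <- record$seed
  train_model(split, record$arch,
    arch_dims(record$nd, record$nh, ni = record$ni, nc = record$nc),
    config = cfg, on_divergence = "flag"
  )
}

#' Predict classes for every window of a dataset
#'
#' @param object A `har_model`.
#' @param data Dataset tibble (typically a z-scored partition).
#' @param ... Unused.
#' @return Tibble with window_id, truth and predicted class.
#' @export
predict.har_model <- function(object, data, ...) {
  arr <- as_window_array(data)
  X <- suffix_array(arr$X, object$dims$nd)
  tibble(
    window_id = arr$ids, truth = arr$labels,
    predicted = predict_batch(object$params, X)
  )
}

#' Confusion matrix of a model on a labeled dataset
#'
#' Rows are true classes, columns predictions; row percentages are
#' `100 * counts / row total`.
#'
#' @param model A `har_model`.
#' @param data Dataset tibble.
#' @param empty_classes `"error"` (default) aborts when a class has no
#'   windows in `data`; `"zero"` keeps an all-zero row (percentages 0).
#' @return A `har_confusion`: list with integer `counts` and numeric
#'   `row_percentages` matrices.
#' @export
confusion_matrix <- function(model, data, empty_classes = c("error", "zero")) {
  empty_classes <- match.arg(empty_classes)
  if (nrow(data) == 0) abort("dataset is empty.")
  preds <- predict(model, data)
  lev <- seq_len(model$dims$nc)
  counts <- table(
    factor(preds$truth, levels = lev),
    factor(preds$predicted, levels = lev)
  )
  counts <- matrix(as.integer(counts), length(lev), length(lev),
    dimnames = list(true = lev, predicted = lev)
  )
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    if (empty_classes == "error") {
      abort(sprintf("class %s has no windows in the dataset.", paste(lev[rs == 0], collapse = ", ")))
    }
    warn("classes with no windows get all-zero percentage rows.")
  }
  pct <- 100 * counts / ifelse(rs == 0, 1, rs)
  structure(
    list(counts = counts, row_percentages = pct, n = sum(counts)),
    class = "har_confusion"
  )
}

#' @export
print.har_confusion <- function(x, ...) {
  cat("<har_confusion> counts (rows = true):\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.har_confusion <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "n")) %>%
    dplyr::mutate(
      true = as.integer(as.character(.data$true)),
      predicted = as.integer(as.character(.data$predicted)),
      pct = as.vector(t(x$row_percentages))[
        (.data$true - 1) * ncol(x$counts) + .data$predicted
      ]
    )
}
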