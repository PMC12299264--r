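test_that("analytic gradients match central finite differences", {
  dims <- arch_dims(nd = 3, nh = 2, ni = 2, nc = 3)
  set.seed(17)
  X <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  y <- c(1L, 2L, 3L, 1L)
  for (arch in c("firnn", "lstm", "gru")) {
    for (draw in 1:5) {
      p <- inflate_params(init_params(arch, dims, seed = draw * 13), 8)
      lg <- harlrp:::loss_and_grads(p, X, y)
      num <- oracle_numerical_grad(p, X, y)
      ana <- harlrp:::flatten_params(lg$grads)
      expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-5)
    }
  }
  # the tanh FIRNN variant has its own hidden derivative
  p <- inflate_params(init_params("firnn", dims, seed = 3, hidden_activation = "tanh"), 8)
  lg <- harlrp:::loss_and_grads(p, X, y)
  num <- oracle_numerical_grad(p, X, y)
  expect_lt(max(abs(harlrp:::flatten_params(lg$grads) - num)) / max(abs(num)), 1e-5)
})

test_that("training on separable planted data reaches perfect training accuracy", {
  sp <- make_tiny_split(n_per_class = 14, fs = 100, window_s = 1, noise_sd = 0.02, seed = 2)
  m <- train_model(
    sp, "lstm", arch_dims(nd = 30, nh = 4),
    train_config(learning_rate = 3e-2, max_epochs = 600, patience = 150, seed = 2)
  )
  expect_equal(m$record$train_acc, 1)
})

test_that("a zero-like learning rate leaves parameters at initialization", {
  sp <- make_tiny_split(n_per_class = 8, seed = 3)
  cfg <- train_config(learning_rate = 1e-30, max_epochs = 2, seed = 4)
  m <- train_model(sp, "gru", arch_dims(nd = 5, nh = 2), cfg)
  init <- init_params("gru", arch_dims(nd = 5, nh = 2), seed = 4)
  expect_equal(
    harlrp:::flatten_params(m$params),
    harlrp:::flatten_params(init),
    tolerance = 1e-12
  )
  expect_error(train_config(learning_rate = 0), "positive")
})

test_that("training is reproducible from its seed", {
  sp <- make_tiny_split(n_per_class = 8, seed = 5)
  cfg <- train_config(learning_rate = 5e-3, max_epochs = 5, seed = 21)
  m1 <- train_model(sp, "firnn", arch_dims(nd = 8, nh = 2), cfg)
  m2 <- train_model(sp, "firnn", arch_dims(nd = 8, nh = 2), cfg)
  expect_identical(m1$record$checksum, m2$record$checksum)
  expect_equal(m1$record, m2$record)
})

test_that("grid plans enumerate the full factorial design", {
  paper <- grid_spec()
  expect_equal(nrow(grid_plan(paper)), 16500)
  expect_equal(length(paper$delays), 11)
  small <- grid_spec(
    architectures = c("firnn", "gru"), delays = c(2, 4),
    hidden_sizes = c(2, 3), repetitions = 3, base_seed = 9
  )
  plan <- grid_plan(small)
  expect_equal(nrow(plan), 24)
  expect_equal(nrow(dplyr::distinct(plan, arch, nd, nh, repetition)), 24)
  expect_true(all(plan$seed >= 0 & plan$seed < 2^31))
  expect_equal(anyDuplicated(plan$seed), 0)
  single <- grid_spec(architectures = "lstm", delays = 5, hidden_sizes = 2, repetitions = 1)
  expect_equal(nrow(grid_plan(single)), 1)
})

test_that("run_grid yields one record per cell and is deterministic", {
  sp <- make_tiny_split(n_per_class = 8, seed = 6)
  spec <- grid_spec(
    architectures = c("firnn", "gru"), delays = c(3, 5),
    hidden_sizes = 2, repetitions = 2, base_seed = 1
  )
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 3, patience = 2)
  res <- run_grid(sp, spec, cfg)
  expect_equal(nrow(res), 8)
  expect_true(all(res$val_acc >= 0 & res$val_acc <= 1))
  res2 <- run_grid(sp, spec, cfg)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("best-run selection maximizes validation accuracy with stated tie-breaks", {
  rec <- function(arch, val, npar, seed) {
    tibble::tibble(
      arch = arch, nd = 2, nh = 2, repetition = 1, ni = 6, nc = 3,
      seed = seed, train_acc = 1, val_acc = val, test_acc = 1,
      epochs = 1, n_params = npar, checksum = "x", diverged = FALSE
    )
  }
  res <- dplyr::bind_rows(
    rec("gru", 0.90, 543, 1), rec("gru", 0.95, 713, 2), rec("gru", 0.93, 543, 3)
  )
  expect_equal(select_best(res, "gru")$seed, 2)
  res <- dplyr::bind_rows(rec("gru", 0.95, 543, 5), rec("gru", 0.95, 713, 4))
  expect_equal(select_best(res, "gru")$n_params, 543)
  res <- dplyr::bind_rows(rec("gru", 0.95, 543, 5), rec("gru", 0.95, 543, 4))
  expect_equal(select_best(res, "gru")$seed, 4)
  expect_equal(select_best(rec("gru", 0.5, 543, 1), "gru")$seed, 1)
  expect_error(select_best(res, "lstm"), "no")
})

test_that("confusion matrices count and percentage correctly", {
  sp <- make_tiny_split(n_per_class = 8, seed = 7)
  m <- train_model(
    sp, "firnn", arch_dims(nd = 5, nh = 2),
    train_config(max_epochs = 2, patience = 2)
  )
  # hand-checkable counts via an injected prediction table
  cm <- confusion_matrix(m, dplyr::bind_rows(sp$train, sp$val, sp$test))
  expect_equal(sum(cm$counts), 24)
  expect_true(all(abs(rowSums(cm$row_percentages) - 100) < 1e-9))
  td <- tidy(cm)
  expect_equal(sum(td$n), 24)
})

test_that("the confusion arithmetic matches a hand count", {
  # true (1,1,2,3), predicted (1,2,2,3)
  counts <- table(factor(c(1, 1, 2, 3), levels = 1:3), factor(c(1, 2, 2, 3), levels = 1:3))
  expect_equal(as.vector(counts[1, ]), c(1, 1, 0))
  expect_equal(as.vector(counts[2, ]), c(0, 1, 0))
  pct <- 100 * counts / rowSums(counts)
  expect_equal(as.vector(pct[1, ]), c(50, 50, 0))
})

test_that("refitting a grid record reproduces the recorded model", {
  sp <- make_tiny_split(n_per_class = 8, seed = 8)
  spec <- grid_spec(
    architectures = "gru", delays = 4, hidden_sizes = 2,
    repetitions = 2, base_seed = 3
  )
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 4, patience = 3)
  res <- run_grid(sp, spec, cfg)
  best <- select_best(res, "gru")
  model <- refit_run(sp, best, cfg)
  expect_identical(model$record$checksum, best$checksum)
})
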