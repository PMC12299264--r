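fake_map <- function(input_rel, hidden_rel = input_rel) {
  structure(
    list(
      arch = "firnn", input_rel = input_rel, hidden_rel = hidden_rel,
      output_rel = c(1, 0, 0), bias_absorbed = 0, target = 1L,
      epsilon = 1e-6, gate_policy = "signal-takes-all", window_id = "w"
    ),
    class = "har_relevance"
  )
}

test_that("the dense epsilon rule handles single paths and symmetric splits", {
  one <- lrp_dense(1, matrix(1, 1, 1), 1, epsilon = 1e-6)
  expect_equal(one$relevance, 1 / (1 + 1e-6), tolerance = 1e-12)
  two <- lrp_dense(c(1, 1), matrix(c(1, 1), 2, 1), 1, epsilon = 1e-6)
  expect_equal(two$relevance[1], two$relevance[2])
  expect_equal(sum(two$relevance), 2 / (2 + 1e-6), tolerance = 1e-12)
  expect_error(lrp_dense(c(1, 1), matrix(1, 1, 1), 1), "shape")
})

test_that("dense propagation conserves relevance up to the absorbed bias", {
  set.seed(7)
  for (rep in 1:5) {
    # well-conditioned layer: pre-activations of order one, so the only
    # deviation is the epsilon term itself
    x <- abs(rnorm(4)) + 0.5
    W <- matrix(abs(rnorm(12)) + 0.3, 4, 3)
    b <- abs(rnorm(3)) * 0.1
    R_up <- abs(rnorm(3))
    out <- lrp_dense(x, W, R_up, bias = b, epsilon = 1e-6)
    # direct summation of the redistribution rule
    expect_lt(
      abs(sum(out$relevance) + out$bias_absorbed - sum(R_up)) / sum(R_up),
      1e-6
    )
    # signed relevance still conserved (up to epsilon) for mixed signs
    xm <- rnorm(4)
    Wm <- matrix(rnorm(12), 4, 3)
    outm <- lrp_dense(xm, Wm, R_up, bias = b, epsilon = 1e-6)
    pre <- colSums(xm * Wm) + b
    exact <- sum(R_up * pre / (pre + 1e-6 * sign(pre)))
    expect_equal(sum(outm$relevance) + outm$bias_absorbed, exact, tolerance = 1e-9)
  }
})

test_that("a single FIR tap receives all input relevance", {
  dims <- arch_dims(nd = 4, nh = 1, ni = 6, nc = 3)
  p <- init_params("firnn", dims, seed = 1)
  p$W1 <- array(0, dim = dim(p$W1))
  p$W1[5, 1, 1] <- 1 # gyr_y at the readout sample
  p$b1 <- 0
  p$W2 <- matrix(c(1, 0, 0), 1, 3)
  p$b2 <- rep(0, 3)
  x <- matrix(rnorm(8 * 6), 8, 6)
  x[8, 5] <- 0.9
  m <- lrp_firnn(p, firnn_forward(p, x), lrp_config())
  nz <- which(abs(m$input_rel) > 1e-12, arr.ind = TRUE)
  expect_equal(nrow(nz), 1)
  expect_equal(unname(nz[1, ]), c(8L, 5L))
})

test_that("total propagated relevance matches the seed for all architectures", {
  set.seed(5)
  dims <- arch_dims(nd = 4, nh = 3, ni = 2, nc = 3)
  x <- matrix(rnorm(8 * 2), 8, 2)
  for (arch in c("firnn", "lstm", "gru")) {
    for (policy in c("signal-takes-all", "proportional")) {
      p <- inflate_params(init_params(arch, dims, seed = 8), 20)
      m <- lrp_relevance(p, x, lrp_config(epsilon = 1e-6, gate_policy = policy))
      seed_val <- sum(m$output_rel)
      recovered <- sum(m$input_rel) + m$bias_absorbed
      expect_lt(abs(seed_val - recovered) / abs(seed_val), 1e-3)
    }
  }
})

test_that("epsilon leakage shrinks monotonically as epsilon goes to zero", {
  set.seed(9)
  dims <- arch_dims(nd = 3, nh = 3, ni = 2, nc = 3)
  x <- matrix(rnorm(6 * 2), 6, 2)
  for (arch in c("firnn", "lstm", "gru")) {
    p <- inflate_params(init_params(arch, dims, seed = 4), 20)
    leaks <- sapply(c(1e-2, 1e-4, 1e-6, 1e-9, 1e-12), function(eps) {
      m <- lrp_relevance(p, x, lrp_config(epsilon = eps))
      abs(sum(m$output_rel) - sum(m$input_rel) - m$bias_absorbed)
    })
    expect_true(all(diff(leaks) < 0))
    expect_lt(leaks[length(leaks)], 1e-9)
  }
})

test_that("a GRU with a fully open update path reduces to dense propagation", {
  # u ~ 0, single step: hidden = tanh(Wx x - b), exactly one affine layer
  dims <- arch_dims(nd = 1, nh = 3, ni = 4, nc = 3)
  p <- inflate_params(init_params("gru", dims, seed = 6), 10)
  p$b_U <- rep(40, 3) # update gate ~ 0
  x <- matrix(rnorm(4), 1, 4)
  tr <- gru_forward(p, x)
  m <- lrp_gated(p, tr, lrp_config())
  # reference: dense pass output -> hidden, then hidden -> input
  out <- lrp_dense(as.numeric(tr$H[1, ]), p$W2, m$output_rel, bias = p$b2)
  ref <- lrp_dense(as.numeric(x), t(p$Wx_C), out$relevance,
    bias = p$b_C, bias_sign = -1
  )
  expect_equal(as.numeric(m$input_rel[1, ]), ref$relevance, tolerance = 1e-4)
})

test_that("a closed forget gate severs relevance flow to earlier steps", {
  dims <- arch_dims(nd = 5, nh = 2, ni = 2, nc = 3)
  p <- inflate_params(init_params("lstm", dims, seed = 7), 10)
  p$b_F <- rep(40, 2) # forget ~ 0: cell only remembers the current write
  for (g in c("I", "F", "O", "C")) p[[paste0("Wh_", g)]][] <- 0 # no hidden path
  x <- matrix(rnorm(10 * 2), 10, 2)
  m <- lrp_gated(p, lstm_forward(p, x), lrp_config())
  expect_true(all(abs(m$input_rel[1:9, ]) < 1e-9))
  expect_gt(sum(abs(m$input_rel[10, ])), 0)
})

test_that("permuting input channels permutes global relevance identically", {
  set.seed(11)
  perm <- c(3, 1, 2, 6, 4, 5)
  x <- matrix(rnorm(9 * 6), 9, 6)
  dims <- arch_dims(nd = 4, nh = 3, ni = 6, nc = 3)
  for (arch in c("firnn", "gru")) {
    p <- inflate_params(init_params(arch, dims, seed = 12), 10)
    v <- normalize_global(lrp_relevance(p, x, lrp_config()), "input")
    p2 <- p
    if (arch == "firnn") {
      p2$W1 <- p$W1[perm, , , drop = FALSE]
    } else {
      for (g in c("U", "R", "C")) {
        p2[[paste0("Wx_", g)]] <- p[[paste0("Wx_", g)]][, perm, drop = FALSE]
      }
    }
    x2 <- x[, perm, drop = FALSE]
    v2 <- normalize_global(lrp_relevance(p2, x2, lrp_config()), "input")
    expect_equal(unname(v2), unname(v[perm]), tolerance = 1e-9)
  }
})

test_that("temporal and global normalizations match hand evaluation", {
  # two channels over two steps, |R| per channel: (1,1) and (2,0)
  R <- cbind(c(1, 1), c(2, 0))
  m <- fake_map(R)
  Tm <- normalize_temporal(m, "input")
  expect_equal(unname(Tm), cbind(c(0.25, 0.25), c(0.5, 0)), ignore_attr = TRUE)
  expect_equal(sum(Tm), 1, tolerance = 1e-9)
  V <- normalize_global(m, "input")
  expect_equal(unname(V), c(0.5, 0.5))
  expect_equal(sum(V), 1, tolerance = 1e-9)
  # V equals the row sums (over time) of the temporal matrix
  expect_equal(unname(V), unname(colSums(Tm)))
  # single nonzero cell concentrates all mass
  single <- fake_map(cbind(c(0, 0), c(0, 3)))
  expect_equal(max(normalize_temporal(single, "input")), 1)
  expect_error(normalize_temporal(fake_map(cbind(0, 0))), "degenerate")
})

test_that("class-wise averaging uses correct predictions and renormalizes", {
  v <- list(
    c(a = 0.6, b = 0.4), c(a = 0.2, b = 0.8), # class 1, both correct
    c(a = 1, b = 0), # class 2, misclassified
    c(a = 0.3, b = 0.7) # class 2, correct
  )
  labels <- c(1, 1, 2, 2)
  preds <- c(1, 1, 1, 2)
  M <- classwise_mean_relevance(v, labels, preds)
  expect_equal(unname(M[, "1"]), c(0.4, 0.6))
  expect_equal(unname(M[, "2"]), c(0.3, 0.7))
  expect_true(all(abs(colSums(M) - 1) < 1e-9))
  expect_warning(
    classwise_mean_relevance(v, labels, c(1, 1, 1, 1)),
    "class 2"
  )
  # single sample per class: columns equal that sample's vector
  M1 <- classwise_mean_relevance(v[c(1, 4)], c(1, 2), c(1, 2))
  expect_equal(unname(M1[, "1"]), c(0.6, 0.4))
})

test_that("gated LRP with open gates reduces to ungated linear propagation", {
  # GRU, u ~ 0 and r ~ 1 over several steps with zero recurrent weights:
  # each step is an independent dense layer; only the last step's hidden
  # state reaches the output, so all input relevance sits at the last row
  dims <- arch_dims(nd = 3, nh = 2, ni = 3, nc = 3)
  p <- inflate_params(init_params("gru", dims, seed = 2), 10)
  p$b_U <- rep(40, 2)
  for (g in c("U", "R", "C")) p[[paste0("Wh_", g)]][] <- 0
  x <- matrix(rnorm(9), 3, 3)
  m <- lrp_gated(p, gru_forward(p, x), lrp_config())
  expect_true(all(abs(m$input_rel[1:2, ]) < 1e-12))
  out <- lrp_dense(
    as.numeric(gru_forward(p, x)$H[3, ]), p$W2,
    m$output_rel,
    bias = p$b2
  )
  ref <- lrp_dense(as.numeric(x[3, ]), t(p$Wx_C), out$relevance,
    bias = p$b_C, bias_sign = -1
  )
  expect_equal(as.numeric(m$input_rel[3, ]), ref$relevance, tolerance = 1e-4)
})
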