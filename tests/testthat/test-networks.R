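test_that("parameter counts match the closed-form weight formulas", {
  dims <- arch_dims(nd = 100, nh = 10)
  expect_equal(n_params(init_params("firnn", dims)), 6043)
  expect_equal(n_params(init_params("gru", dims)), 543)
  expect_equal(n_params(init_params("lstm", dims)), 713)
  # cross-module identity over a small lattice
  for (arch in c("firnn", "lstm", "gru")) {
    for (nd in c(1, 3)) {
      for (nh in c(1, 4)) {
        d <- arch_dims(nd = nd, nh = nh, ni = 2, nc = 3)
        expect_equal(
          n_params(init_params(arch, d)),
          complexity_profile(arch, d)$n_weights
        )
      }
    }
  }
})

test_that("initialization is seeded and has the scaled-normal spread", {
  dims <- arch_dims(nd = 50, nh = 10)
  p1 <- init_params("lstm", dims, seed = 5)
  p2 <- init_params("lstm", dims, seed = 5)
  expect_identical(p1, p2)
  p3 <- init_params("lstm", dims, seed = 6)
  expect_false(identical(p1, p3))
  draws <- harlrp:::flatten_params(init_params("firnn", arch_dims(nd = 100, nh = 10), seed = 1))
  expect_equal(sd(draws), sqrt(0.001), tolerance = 0.05)
  expect_equal(mean(draws), 0, tolerance = 0.005)
  expect_error(init_params("cnn", dims), "arg")
})

test_that("zero parameters give the symmetric fixed point", {
  dims <- arch_dims(nd = 4, nh = 3, ni = 2, nc = 3)
  x <- matrix(rnorm(8 * 2), 8, 2)
  for (arch in c("firnn", "lstm", "gru")) {
    p <- init_params(arch, dims, seed = 1)
    for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
    tr <- forward_trace(p, x)
    expect_equal(tr$probs, rep(1 / 3, 3), tolerance = 1e-12)
    if (arch == "firnn") {
      expect_equal(as.numeric(tr$hidden), rep(0.5, 3), tolerance = 1e-12)
    }
    if (arch == "lstm") {
      # gates 0.5, candidate 0: the cell state stays at 0
      expect_true(all(abs(tr$C) < 1e-12))
      expect_equal(as.numeric(tr$I), rep(0.5, 4 * 3), tolerance = 1e-12)
    }
  }
})

test_that("forward passes equal brute-force scalar oracles", {
  set.seed(31)
  for (rep in 1:3) {
    dims <- arch_dims(nd = 5, nh = 3, ni = 3, nc = 3)
    x <- matrix(rnorm(12 * 3), 12, 3)
    xs <- x[8:12, , drop = FALSE]

    p <- inflate_params(init_params("firnn", dims, seed = rep), 10)
    tr <- firnn_forward(p, x)
    expect_lt(max(abs(oracle_firnn_pre(p, x, dims) - tr$pre_h)), 1e-12)

    p <- inflate_params(init_params("lstm", dims, seed = rep), 10)
    tr <- lstm_forward(p, x)
    st <- oracle_lstm_states(p, xs)
    for (t in 1:5) {
      expect_lt(max(abs(st[[t]]$h - tr$H[t, ])), 1e-12)
      expect_lt(max(abs(st[[t]]$c - tr$C[t, ])), 1e-12)
    }

    p <- inflate_params(init_params("gru", dims, seed = rep), 10)
    tr <- gru_forward(p, x)
    st <- oracle_gru_states(p, xs)
    for (t in 1:5) expect_lt(max(abs(st[[t]]$h - tr$H[t, ])), 1e-12)
  }
})

test_that("saturated gates reproduce the gating identities", {
  dims <- arch_dims(nd = 5, nh = 2, ni = 2, nc = 3)
  x <- matrix(rnorm(10 * 2), 10, 2)
  # LSTM: forget ~ 1, input ~ 0 freezes the cell state
  p <- inflate_params(init_params("lstm", dims, seed = 2), 5)
  p$b_F <- rep(-40, 2) # pre = z + 40 -> sigmoid ~ 1
  p$b_I <- rep(40, 2) # pre = z - 40 -> sigmoid ~ 0
  tr <- lstm_forward(p, x)
  expect_true(all(abs(tr$C) < 1e-12)) # cell frozen at its zero start
  # GRU: update ~ 1 keeps the hidden state at zero
  p <- inflate_params(init_params("gru", dims, seed = 3), 5)
  p$b_U <- rep(-40, 2)
  tr <- gru_forward(p, x)
  expect_true(all(abs(tr$H) < 1e-12))
  # GRU: update ~ 0 makes hidden equal the candidate at every step
  p$b_U <- rep(40, 2)
  tr <- gru_forward(p, x)
  expect_lt(max(abs(tr$H - tr$G)), 1e-9)
})

test_that("gate activations live in (0,1) and probabilities sum to 1", {
  dims <- arch_dims(nd = 6, nh = 3, ni = 2, nc = 3)
  for (seed in 1:5) {
    x <- matrix(rnorm(12 * 2, sd = 2), 12, 2)
    p <- inflate_params(init_params("lstm", dims, seed = seed), 30)
    tr <- lstm_forward(p, x)
    for (g in list(tr$I, tr$F, tr$O)) {
      expect_true(all(g > 0 & g < 1))
    }
    expect_true(all(abs(tr$G) < 1))
    expect_equal(sum(tr$probs), 1, tolerance = 1e-12)
  }
})

test_that("softmax is shift-invariant and matches the hand example", {
  tr <- structure(
    list(logits = c(0, 0, log(2)), probs = as.numeric(harlrp:::softmax(c(0, 0, log(2))))),
    class = "har_trace"
  )
  expect_equal(tr$probs, c(0.25, 0.25, 0.5), tolerance = 1e-12)
  expect_equal(predict_class(tr), 3)
  shifted <- as.numeric(harlrp:::softmax(c(0, 0, log(2)) + 1234))
  expect_equal(shifted, tr$probs, tolerance = 1e-12)
  big <- as.numeric(harlrp:::softmax(c(1e6, 1e6 - 1, 0)))
  expect_true(all(is.finite(big)))
})

test_that("prediction breaks ties toward the lowest class id", {
  tr <- structure(list(probs = c(0.2, 0.5, 0.3)), class = "har_trace")
  expect_equal(predict_class(tr), 2)
  tr$probs <- rep(1 / 3, 3)
  expect_equal(predict_class(tr), 1)
})

test_that("windows shorter than the delay count are rejected", {
  dims <- arch_dims(nd = 50, nh = 2, ni = 6, nc = 3)
  p <- init_params("firnn", dims)
  x <- matrix(rnorm(30 * 6), 30, 6)
  expect_error(firnn_forward(p, x), "delays")
})

test_that("the tanh hidden variant changes the FIRNN response accordingly", {
  dims <- arch_dims(nd = 3, nh = 2, ni = 2, nc = 3)
  ps <- init_params("firnn", dims, seed = 4, hidden_activation = "sigmoid")
  pt <- init_params("firnn", dims, seed = 4, hidden_activation = "tanh")
  x <- matrix(rnorm(6 * 2), 6, 2)
  trs <- firnn_forward(ps, x)
  trt <- firnn_forward(pt, x)
  expect_equal(trs$pre_h, trt$pre_h, tolerance = 1e-12)
  expect_equal(as.numeric(trt$hidden), tanh(trt$pre_h), tolerance = 1e-12)
  expect_equal(as.numeric(trs$hidden), 1 / (1 + exp(-trs$pre_h)), tolerance = 1e-12)
})
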