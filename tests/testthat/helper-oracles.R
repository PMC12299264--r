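# Independent brute-force oracles: scalar loops, deliberately free of the
# package's vectorized implementation paths.

sig_ <- function(z) 1 / (1 + exp(-z))

# FIRNN hidden pre-activations at readout, by explicit double loop.
oracle_firnn_pre <- function(params, x, dims) {
  n_t <- nrow(x)
  pre <- numeric(dims$nh)
  for (h in seq_len(dims$nh)) {
    s <- 0
    for (i in seq_len(dims$ni)) {
      for (j in seq_len(dims$nd)) {
        s <- s + params$W1[i, j, h] * x[n_t - j + 1, i]
      }
    }
    pre[h] <- s - params$b1[h]
  }
  pre
}

# LSTM per-step states by explicit recurrence on vectors.
oracle_lstm_states <- function(params, xs) {
  nh <- length(params$b_I)
  h <- numeric(nh)
  cc <- numeric(nh)
  out <- list()
  for (t in seq_len(nrow(xs))) {
    xi <- xs[t, ]
    gi <- sig_(params$Wx_I %*% xi + params$Wh_I %*% h - params$b_I)
    gf <- sig_(params$Wx_F %*% xi + params$Wh_F %*% h - params$b_F)
    go <- sig_(params$Wx_O %*% xi + params$Wh_O %*% h - params$b_O)
    gg <- tanh(params$Wx_C %*% xi + params$Wh_C %*% h - params$b_C)
    cc <- as.numeric(gf * cc + gi * gg)
    h <- as.numeric(go * tanh(cc))
    out[[t]] <- list(h = h, c = cc)
  }
  out
}

oracle_gru_states <- function(params, xs) {
  nh <- length(params$b_U)
  h <- numeric(nh)
  out <- list()
  for (t in seq_len(nrow(xs))) {
    xi <- xs[t, ]
    gu <- sig_(params$Wx_U %*% xi + params$Wh_U %*% h - params$b_U)
    gr <- sig_(params$Wx_R %*% xi + params$Wh_R %*% h - params$b_R)
    gg <- tanh(params$Wx_C %*% xi + params$Wh_C %*% (gr * h) - params$b_C)
    h <- as.numeric(gu * h + (1 - gu) * gg)
    out[[t]] <- list(h = h)
  }
  out
}

# Central finite-difference gradient of the batch loss.
oracle_numerical_grad <- function(params, X, y, h_step = 1e-6) {
  theta <- harlrp:::flatten_params(params)
  num <- numeric(length(theta))
  for (k in seq_along(theta)) {
    tp <- theta
    tp[k] <- tp[k] + h_step
    tm <- theta
    tm[k] <- tm[k] - h_step
    lp <- harlrp:::loss_and_grads(harlrp:::unflatten_params(tp, params), X, y)$loss
    lm <- harlrp:::loss_and_grads(harlrp:::unflatten_params(tm, params), X, y)$loss
    num[k] <- (lp - lm) / (2 * h_step)
  }
  num
}

# Small planted-channel split for training tests: short windows keep the
# recurrences cheap.
make_tiny_split <- function(n_per_class = 12, fs = 25, window_s = 1,
                            noise_sd = 0.1, seed = 1) {
  cfg <- har_generator_config(
    n_per_class = n_per_class,
    class_specs = planted_class_specs("gyr_y"),
    fs = fs, window_s = window_s, noise_sd = noise_sd, seed = seed
  )
  generate_dataset(cfg) |>
    filter_zero_rows() |>
    balance_classes(seed = seed) |>
    split_dataset(seed = seed) |>
    zscore_per_class()
}

# Scale a parameter set so activations leave the linear regime.
inflate_params <- function(params, factor = 20) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] * factor
  params
}
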