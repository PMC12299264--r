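# Analytic gradients of the mean categorical cross-entropy with respect to
# every parameter block. Backpropagation is through the FIR taps for the
# FIRNN and through time for LSTM/GRU. Verified against central finite
# differences in the test suite.

loss_and_grads <- function(params, X, y) {
  arch <- attr(params, "arch")
  n <- dim(X)[1]
  fwd <- net_forward(params, X)
  nc <- ncol(fwd$probs)
  Y <- matrix(0, n, nc)
  Y[cbind(seq_len(n), y)] <- 1
  p_true <- fwd$probs[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(p_true, 1e-300)))
  dlogits <- (fwd$probs - Y) / n
  grads <- switch(arch,
    firnn = firnn_grads(params, fwd, dlogits),
    lstm = lstm_grads(params, fwd, dlogits),
    gru = gru_grads(params, fwd, dlogits)
  )
  list(loss = loss, grads = grads, probs = fwd$probs)
}

firnn_grads <- function(params, fwd, dlogits) {
  dW2 <- t(fwd$hidden) %*% dlogits
  db2 <- colSums(dlogits)
  dhidden <- dlogits %*% t(params$W2)
  act <- attr(params, "hidden_activation") %||% "sigmoid"
  dpre <- if (act == "tanh") {
    dhidden * (1 - fwd$hidden^2)
  } else {
    dhidden * fwd$hidden * (1 - fwd$hidden)
  }
  dWmat <- t(fwd$Xmat) %*% dpre
  list(
    W1 = array(dWmat, dim = dim(params$W1)),
    b1 = -colSums(dpre),
    W2 = dW2, b2 = db2
  )
}

lstm_grads <- function(params, fwd, dlogits) {
  X <- fwd$X
  d <- dim(X)
  n <- d[1]; nd <- d[2]
  nh <- length(params$b_I)
  g <- purrr::map(unclass(params), ~ array(0, dim = dim(.x) %||% length(.x)))
  H_last <- matrix(fwd$H[, nd, ], n, nh)
  g$W2 <- t(H_last) %*% dlogits
  g$b2 <- colSums(dlogits)
  dH <- dlogits %*% t(params$W2)
  dC <- matrix(0, n, nh)
  sl <- function(a, t) matrix(a[, t, ], n, nh)
  for (t in nd:1) {
    gI <- sl(fwd$I, t); gF <- sl(fwd$F, t); gO <- sl(fwd$O, t); gG <- sl(fwd$G, t)
    C_t <- sl(fwd$C, t)
    C_prev <- if (t > 1) sl(fwd$C, t - 1) else matrix(0, n, nh)
    H_prev <- if (t > 1) sl(fwd$H, t - 1) else matrix(0, n, nh)
    x_t <- slab(X, t)
    tc <- tanh(C_t)
    dO <- dH * tc
    dC <- dC + dH * gO * (1 - tc^2)
    dF <- dC * C_prev
    dI <- dC * gG
    dG <- dC * gI
    da_i <- dI * gI * (1 - gI)
    da_f <- dF * gF * (1 - gF)
    da_o <- dO * gO * (1 - gO)
    da_g <- dG * (1 - gG^2)
    acc <- function(tag, da) {
      g[[paste0("Wx_", tag)]] <<- g[[paste0("Wx_", tag)]] + t(da) %*% x_t
      g[[paste0("Wh_", tag)]] <<- g[[paste0("Wh_", tag)]] + t(da) %*% H_prev
      g[[paste0("b_", tag)]] <<- g[[paste0("b_", tag)]] - colSums(da)
    }
    acc("I", da_i); acc("F", da_f); acc("O", da_o); acc("C", da_g)
    dH <- da_i %*% params$Wh_I + da_f %*% params$Wh_F +
      da_o %*% params$Wh_O + da_g %*% params$Wh_C
    dC <- dC * gF
  }
  g
}

gru_grads <- function(params, fwd, dlogits) {
  X <- fwd$X
  d <- dim(X)
  n <- d[1]; nd <- d[2]
  nh <- length(params$b_U)
  g <- purrr::map(unclass(params), ~ array(0, dim = dim(.x) %||% length(.x)))
  sl <- function(a, t) matrix(a[, t, ], n, nh)
  H_last <- sl(fwd$H, nd)
  g$W2 <- t(H_last) %*% dlogits
  g$b2 <- colSums(dlogits)
  dH <- dlogits %*% t(params$W2)
  for (t in nd:1) {
    gU <- sl(fwd$U, t); gR <- sl(fwd$R, t); gG <- sl(fwd$G, t)
    H_prev <- if (t > 1) sl(fwd$H, t - 1) else matrix(0, n, nh)
    x_t <- slab(X, t)
    dU <- dH * (H_prev - gG)
    dG <- dH * (1 - gU)
    dH_prev <- dH * gU
    da_g <- dG * (1 - gG^2)
    g$Wx_C <- g$Wx_C + t(da_g) %*% x_t
    g$Wh_C <- g$Wh_C + t(da_g) %*% (gR * H_prev)
    g$b_C <- g$b_C - colSums(da_g)
    dRH <- da_g %*% params$Wh_C
    dR <- dRH * H_prev
    dH_prev <- dH_prev + dRH * gR
    da_u <- dU * gU * (1 - gU)
    da_r <- dR * gR * (1 - gR)
    g$Wx_U <- g$Wx_U + t(da_u) %*% x_t
    g$Wh_U <- g$Wh_U + t(da_u) %*% H_prev
    g$b_U <- g$b_U - colSums(da_u)
    g$Wx_R <- g$Wx_R + t(da_r) %*% x_t
    g$Wh_R <- g$Wh_R + t(da_r) %*% H_prev
    g$b_R <- g$b_R - colSums(da_r)
    dH <- dH_prev + da_u %*% params$Wh_U + da_r %*% params$Wh_R
  }
  g
}
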