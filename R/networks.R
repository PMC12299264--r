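#' Architecture dimensions
#'
#' @param ni Number of input channels (default 6).
#' @param nd Delays: FIR tap count for the FIRNN, consumed input-sequence
#'   length (window suffix, in samples) for LSTM/GRU.
#' @param nh Hidden neurons.
#' @param nc Output classes (default 3).
#' @return An object of class `arch_dims`.
#' @export
arch_dims <- function(nd, nh, ni = 6, nc = 3) {
  v <- c(ni = ni, nd = nd, nh = nh, nc = nc)
  if (any(v < 1) || any(v != round(v))) abort("all dimensions must be positive integers.")
  structure(stats::setNames(as.list(as.integer(v)), names(v)), class = "arch_dims")
}

har_architectures <- c("firnn", "lstm", "gru")

#' Initialize network parameters
#'
#' Every weight and bias is drawn i.i.d. from a zero-mean normal with
#' variance 0.001 (sigma = sqrt(0.001)), a scale small enough to avoid
#' early activation saturation. The total number of scalars equals the
#' closed-form trainable-weight count of [complexity_profile()] for the
#' same architecture and dimensions.
#'
#' Parameter blocks: FIRNN has the FIR tensor `W1` (ni x nd x nh), hidden
#' bias `b1`, output layer `W2` (nh x nc), `b2`. LSTM has per-gate input
#' weights `Wx_*` (nh x ni), recurrent weights `Wh_*` (nh x nh) and biases
#' `b_*` for the input (I), forget (F), output (O) gates and cell candidate
#' (C); GRU the same for update (U), reset (R) and candidate (C). Hidden
#' pre-activations subtract the bias (`z - b`), the output layer adds it.
#'
#' @param arch One of `"firnn"`, `"lstm"`, `"gru"`.
#' @param dims An [arch_dims()].
#' @param seed RNG seed; identical seeds give identical parameters.
#' @param hidden_activation Activation of the FIRNN hidden layer:
#'   `"sigmoid"` (default) or `"tanh"`. Gated architectures always use
#'   sigmoid gates and tanh candidates/cell outputs.
#' @return A named list of arrays with class `har_params` and attributes
#'   `arch`, `dims` and `hidden_activation`.
#' @export
init_params <- function(arch, dims, seed = 1,
                        hidden_activation = c("sigmoid", "tanh")) {
  arch <- match.arg(arch, har_architectures)
  hidden_activation <- match.arg(hidden_activation)
  if (!inherits(dims, "arch_dims")) abort("`dims` must be an arch_dims.")
  sdev <- sqrt(0.001)
  ni <- dims$ni; nd <- dims$nd; nh <- dims$nh; nc <- dims$nc
  draw <- function(...) {
    d <- c(...)
    array(rnorm(prod(d), 0, sdev), dim = d)
  }
  params <- withr::with_seed(seed, {
    if (arch == "firnn") {
      list(
        W1 = draw(ni, nd, nh), b1 = as.numeric(draw(nh)),
        W2 = matrix(draw(nh, nc), nh, nc), b2 = as.numeric(draw(nc))
      )
    } else {
      gates <- if (arch == "lstm") c("I", "F", "O", "C") else c("U", "R", "C")
      p <- list()
      for (g in gates) {
        p[[paste0("Wx_", g)]] <- matrix(draw(nh, ni), nh, ni)
        p[[paste0("Wh_", g)]] <- matrix(draw(nh, nh), nh, nh)
        p[[paste0("b_", g)]] <- as.numeric(draw(nh))
      }
      p$W2 <- matrix(draw(nh, nc), nh, nc)
      p$b2 <- as.numeric(draw(nc))
      p
    }
  })
  structure(params,
    class = "har_params", arch = arch, dims = dims,
    hidden_activation = hidden_activation
  )
}

#' Number of trainable scalars in a parameter set
#'
#' @param params A [init_params()] result.
#' @return Integer count.
#' @export
n_params <- function(params) {
  sum(vapply(unclass(params), length, integer(1)))
}

flatten_params <- function(params) {
  unlist(unclass(params), use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  out <- unclass(template)
  pos <- 0L
  for (nm in names(out)) {
    n <- length(out[[nm]])
    v <- theta[pos + seq_len(n)]
    if (is.matrix(out[[nm]]) || is.array(out[[nm]])) {
      out[[nm]] <- array(v, dim = dim(out[[nm]]))
    } else {
      out[[nm]] <- v
    }
    pos <- pos + n
  }
  structure(out,
    class = "har_params",
    arch = attr(template, "arch"), dims = attr(template, "dims"),
    hidden_activation = attr(template, "hidden_activation")
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax.
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# --- batched forward passes ------------------------------------------------
# X is an array (n_samples, nd, ni) holding the consumed window suffix in
# forward time order: X[, t, ] is the input nd - t steps before readout.

net_forward <- function(params, X) {
  arch <- attr(params, "arch")
  switch(arch,
    firnn = firnn_forward_batch(params, X),
    lstm = lstm_forward_batch(params, X),
    gru = gru_forward_batch(params, X)
  )
}

# FIRNN: hidden_h = sigmoid(sum_{i,j} W1[i,j,h] * x_i(n - j + 1) - b1[h])
# at readout time n (the final sample), i.e. tap j reads the input j - 1
# steps back.
firnn_forward_batch <- function(params, X) {
  d <- dim(X)
  n <- d[1]; nd <- d[2]; ni <- d[3]
  nh <- length(params$b1)
  Xrev <- X[, nd:1, , drop = FALSE] # [s, j, i] = x_i(n - j + 1)
  Xmat <- matrix(aperm(Xrev, c(1, 3, 2)), n, ni * nd) # col (j-1)*ni + i
  Wmat <- matrix(params$W1, ni * nd, nh)
  pre_h <- Xmat %*% Wmat - matrix(params$b1, n, nh, byrow = TRUE)
  act <- attr(params, "hidden_activation") %||% "sigmoid"
  hidden <- if (act == "tanh") tanh(pre_h) else sigmoid(pre_h)
  logits <- hidden %*% params$W2 + matrix(params$b2, n, ncol(params$W2), byrow = TRUE)
  list(
    arch = "firnn", X = X, Xmat = Xmat, pre_h = pre_h, hidden = hidden,
    logits = logits, probs = softmax(logits)
  )
}

slab <- function(X, t) {
  # (n, nd, ni) -> (n, ni) matrix at step t
  d <- dim(X)
  matrix(X[, t, , drop = FALSE], d[1], d[3])
}

lstm_forward_batch <- function(params, X) {
  d <- dim(X)
  n <- d[1]; nd <- d[2]
  nh <- length(params$b_I)
  zeros <- function() array(0, c(n, nd, nh))
  st <- list(
    I = zeros(), F = zeros(), O = zeros(), G = zeros(),
    pre_I = zeros(), pre_F = zeros(), pre_O = zeros(), pre_G = zeros(),
    C = zeros(), H = zeros()
  )
  H <- matrix(0, n, nh)
  C <- matrix(0, n, nh)
  for (t in seq_len(nd)) {
    x_t <- slab(X, t)
    aff <- function(g) {
      x_t %*% t(params[[paste0("Wx_", g)]]) + H %*% t(params[[paste0("Wh_", g)]]) -
        matrix(params[[paste0("b_", g)]], n, nh, byrow = TRUE)
    }
    pI <- aff("I"); pF <- aff("F"); pO <- aff("O"); pG <- aff("C")
    gI <- sigmoid(pI); gF <- sigmoid(pF); gO <- sigmoid(pO); gG <- tanh(pG)
    C <- gF * C + gI * gG
    H <- gO * tanh(C)
    st$I[, t, ] <- gI; st$F[, t, ] <- gF; st$O[, t, ] <- gO; st$G[, t, ] <- gG
    st$pre_I[, t, ] <- pI; st$pre_F[, t, ] <- pF; st$pre_O[, t, ] <- pO; st$pre_G[, t, ] <- pG
    st$C[, t, ] <- C; st$H[, t, ] <- H
  }
  logits <- H %*% params$W2 + matrix(params$b2, n, ncol(params$W2), byrow = TRUE)
  c(
    list(arch = "lstm", X = X, logits = logits, probs = softmax(logits)),
    st
  )
}

gru_forward_batch <- function(params, X) {
  d <- dim(X)
  n <- d[1]; nd <- d[2]
  nh <- length(params$b_U)
  zeros <- function() array(0, c(n, nd, nh))
  st <- list(
    U = zeros(), R = zeros(), G = zeros(),
    pre_U = zeros(), pre_R = zeros(), pre_G = zeros(),
    H = zeros()
  )
  H <- matrix(0, n, nh)
  for (t in seq_len(nd)) {
    x_t <- slab(X, t)
    aff <- function(g, h_term) {
      x_t %*% t(params[[paste0("Wx_", g)]]) + h_term %*% t(params[[paste0("Wh_", g)]]) -
        matrix(params[[paste0("b_", g)]], n, nh, byrow = TRUE)
    }
    pU <- aff("U", H); pR <- aff("R", H)
    gU <- sigmoid(pU); gR <- sigmoid(pR)
    pG <- x_t %*% t(params$Wx_C) + (gR * H) %*% t(params$Wh_C) -
      matrix(params$b_C, n, nh, byrow = TRUE)
    gG <- tanh(pG)
    H <- gU * H + (1 - gU) * gG
    st$U[, t, ] <- gU; st$R[, t, ] <- gR; st$G[, t, ] <- gG
    st$pre_U[, t, ] <- pU; st$pre_R[, t, ] <- pR; st$pre_G[, t, ] <- pG
    st$H[, t, ] <- H
  }
  logits <- H %*% params$W2 + matrix(params$b2, n, ncol(params$W2), byrow = TRUE)
  c(
    list(arch = "gru", X = X, logits = logits, probs = softmax(logits)),
    st
  )
}

# --- per-window traces ------------------------------------------------------

window_to_matrix <- function(window, ni = 6) {
  if (is.matrix(window)) {
    if (ncol(window) != ni) {
      abort(sprintf("window matrix must have %d columns.", ni))
    }
    if (ni == 6 && is.null(colnames(window))) colnames(window) <- har_channels()
    return(window)
  }
  validate_har_data(window)
  if (length(unique(window$window_id)) != 1) {
    abort("expected a single window; got several window_ids.")
  }
  window <- dplyr::arrange(window, .data$t_index)
  as.matrix(window[, har_channels()])
}

# Dataset -> array (n, NT, 6) + labels/ids, windows in first-appearance order.
as_window_array <- function(data) {
  validate_har_data(data)
  ids <- unique(data$window_id)
  n_t <- sum(data$window_id == ids[1])
  ord <- order(match(data$window_id, ids), data$t_index)
  m <- as.matrix(data[ord, har_channels()])
  X <- aperm(array(m, c(n_t, length(ids), 6)), c(2, 1, 3))
  labels <- data$class[ord][seq(1, by = n_t, length.out = length(ids))]
  list(X = X, labels = as.integer(labels), ids = ids, n_t = n_t)
}

suffix_array <- function(X, nd) {
  n_t <- dim(X)[2]
  if (nd > n_t) abort(sprintf("window has %d samples but %d delays requested.", n_t, nd))
  X[, (n_t - nd + 1):n_t, , drop = FALSE]
}

make_trace <- function(params, window, dims) {
  x <- window_to_matrix(window, ni = dims$ni)
  nd <- dims$nd
  n_t <- nrow(x)
  if (n_t < nd) abort(sprintf("window has %d samples but %d delays requested.", n_t, nd))
  X <- array(0, c(1, nd, dims$ni))
  X[1, , ] <- x[(n_t - nd + 1):n_t, , drop = FALSE]
  fwd <- net_forward(params, X)
  drop1 <- function(a) {
    if (is.array(a) && length(dim(a)) == 3) {
      return(matrix(a[1, , ], dim(a)[2], dim(a)[3]))
    }
    if (is.matrix(a) && nrow(a) == 1) {
      return(as.numeric(a))
    }
    a
  }
  tr <- purrr::map(fwd[setdiff(names(fwd), c("arch", "X", "logits", "probs"))], drop1)
  structure(
    c(
      list(
        arch = fwd$arch, dims = dims, x = x, rows = (n_t - nd + 1):n_t,
        logits = as.numeric(fwd$logits), probs = as.numeric(fwd$probs)
      ),
      tr
    ),
    class = "har_trace"
  )
}

#' Forward recall of one window
#'
#' Runs a single labeled window through the network and returns the full
#' forward trace: every gate/cell/hidden activation and pre-activation per
#' time step, the output logits and the softmax class probabilities. The
#' trace carries everything relevance propagation needs.
#'
#' `firnn_forward()` computes each hidden unit as a sigmoid of its FIR
#' filter response at the readout time (the window's final sample);
#' `lstm_forward()` and `gru_forward()` run the standard gated recurrences
#' over the last `nd` samples from zero initial state and read out from the
#' final hidden vector.
#'
#' @param params A [init_params()] result of the matching architecture.
#' @param window A single window: `NT x 6` matrix or a one-window slice of
#'   a dataset tibble.
#' @param dims Architecture dimensions; defaults to those stored in
#'   `params`.
#' @return A `har_trace` object.
#' @export
firnn_forward <- function(params, window, dims = attr(params, "dims")) {
  stopifnot(attr(params, "arch") == "firnn")
  make_trace(params, window, dims)
}

#' @rdname firnn_forward
#' @export
lstm_forward <- function(params, window, dims = attr(params, "dims")) {
  stopifnot(attr(params, "arch") == "lstm")
  make_trace(params, window, dims)
}

#' @rdname firnn_forward
#' @export
gru_forward <- function(params, window, dims = attr(params, "dims")) {
  stopifnot(attr(params, "arch") == "gru")
  make_trace(params, window, dims)
}

#' Forward trace for any architecture
#'
#' @inheritParams firnn_forward
#' @export
forward_trace <- function(params, window, dims = attr(params, "dims")) {
  make_trace(params, window, dims)
}

#' Predicted class of a forward trace
#'
#' Argmax of the class probabilities; ties break deterministically to the
#' lowest class id.
#'
#' @param trace A `har_trace`.
#' @return Integer class id.
#' @export
predict_class <- function(trace) {
  which.max(trace$probs)
}

predict_batch <- function(params, X) {
  fwd <- net_forward(params, X)
  max.col(fwd$probs, ties.method = "first")
}
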