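#' Relevance-propagation configuration
#'
#' @param epsilon Stabilizer added to each redistribution denominator,
#'   signed to match the denominator so near-zero sums cannot flip sign
#'   (default 1e-6).
#' @param gate_policy How multiplicative gate-times-signal junctions in
#'   LSTM/GRU pass relevance. `"signal-takes-all"` (default, the
#'   established convention for LRP in gated recurrent networks) sends all
#'   relevance to the signal operand and none to the gate;
#'   `"proportional"` splits by the absolute operand values and propagates
#'   the gate share through the gate's own affine inputs.
#' @param target Seed relevance at the `"predicted"` class (default) or a
#'   `"given"` class supplied via `target_class`.
#' @param target_class Class id used when `target = "given"`.
#' @return An object of class `lrp_config`.
#' @export
lrp_config <- function(epsilon = 1e-6,
                       gate_policy = c("signal-takes-all", "proportional"),
                       target = c("predicted", "given"),
                       target_class = NULL) {
  if (!is.numeric(epsilon) || epsilon <= 0) abort("`epsilon` must be positive.")
  gate_policy <- match.arg(gate_policy)
  target <- match.arg(target)
  if (target == "given" && is.null(target_class)) {
    abort("`target_class` is required when target = \"given\".")
  }
  structure(
    list(
      epsilon = epsilon, gate_policy = gate_policy,
      target = target, target_class = target_class
    ),
    class = "lrp_config"
  )
}

# Signed-epsilon stabilizer: sign(0) counts as +.
stab <- function(z, eps) z + eps * ifelse(z >= 0, 1, -1)

#' Epsilon-rule relevance redistribution through one dense layer
#'
#' Redistributes upper-layer relevance `R_j` to lower-layer neurons in
#' proportion to their contributions `x_i * w_ij`, with the pre-activation
#' (including the bias) as the stabilized denominator. The bias share is
#' absorbed, not redistributed, and is reported so conservation can be
#' audited: `sum(relevance) + bias_absorbed ~ sum(R_upper)` up to the
#' epsilon leakage.
#'
#' @param x Lower-layer activations (length `n_lower`).
#' @param weights `n_lower x n_upper` weight matrix.
#' @param upper_relevance Relevance of the upper layer (length `n_upper`).
#' @param bias Upper-layer bias vector (default zero).
#' @param epsilon Stabilizer.
#' @param bias_sign `+1` when the layer adds its bias (output layer), `-1`
#'   when it subtracts it (hidden layers here).
#' @return List with `relevance` (length `n_lower`) and `bias_absorbed`.
#' @export
lrp_dense <- function(x, weights, upper_relevance, bias = NULL,
                      epsilon = 1e-6, bias_sign = 1) {
  if (length(x) != nrow(weights) || length(upper_relevance) != ncol(weights)) {
    abort("shape mismatch between activations, weights and relevance.")
  }
  if (is.null(bias)) bias <- numeric(ncol(weights))
  Z <- x * weights
  b_term <- bias_sign * bias
  pre <- colSums(Z) + b_term
  f <- upper_relevance / stab(pre, epsilon)
  list(
    relevance = as.numeric(Z %*% f),
    bias_absorbed = sum(b_term * f)
  )
}

# Redistribute gate/candidate relevance through an affine map
# pre = Wx x + Wh hrec - b. Returns input share (per channel), recurrent
# share (per hidden unit of the previous step) and the absorbed bias share.
affine_redistribute <- function(R_up, Wx, x, Wh, hrec, b, pre, eps) {
  f <- R_up / stab(pre, eps)
  list(
    input = as.numeric(crossprod(Wx, f)) * x,
    hidden = as.numeric(crossprod(Wh, f)) * hrec,
    bias = sum(-b * f)
  )
}

# Split relevance of a product a*b between the two operands by |value|;
# all-zero products absorb the relevance (returned as leak).
split_product <- function(R, a, b) {
  tot <- abs(a) + abs(b)
  w <- ifelse(tot > 0, abs(a) / ifelse(tot > 0, tot, 1), 0)
  list(first = R * w, second = R * ifelse(tot > 0, 1 - w, 0))
}

seed_relevance <- function(trace, config) {
  k <- if (config$target == "given") config$target_class else predict_class(trace)
  out <- numeric(length(trace$logits))
  out[k] <- trace$logits[k]
  list(k = k, output_rel = out)
}

new_relevance_map <- function(arch, input_rel, hidden_rel, output_rel,
                              bias_absorbed, target, config, window_id = NULL) {
  if (ncol(input_rel) == 6) colnames(input_rel) <- har_channels()
  structure(
    list(
      arch = arch, input_rel = input_rel, hidden_rel = hidden_rel,
      output_rel = output_rel, bias_absorbed = bias_absorbed,
      target = target, epsilon = config$epsilon,
      gate_policy = config$gate_policy, window_id = window_id
    ),
    class = "har_relevance"
  )
}

#' @export
print.har_relevance <- function(x, ...) {
  cat(sprintf(
    "<har_relevance> %s, target class %d, seed %.4g, input |R| total %.4g, bias absorbed %.4g\n",
    x$arch, x$target, sum(x$output_rel), sum(abs(x$input_rel)), x$bias_absorbed
  ))
  invisible(x)
}

#' Relevance propagation through a FIRNN trace
#'
#' Seeds the target-class logit at the output, pushes it to the hidden
#' units through the dense output layer, then redistributes each hidden
#' unit's relevance across its `ni x nd` FIR-tap contributions
#' `w[i, j, h] * x_i(n - j + 1)`, accumulating signed relevance at each
#' (time, channel) cell of the consumed window suffix.
#'
#' @param params FIRNN parameters.
#' @param trace A [firnn_forward()] trace.
#' @param config An [lrp_config()].
#' @return A `har_relevance` map: `input_rel` is `NT x 6` (zero outside
#'   the consumed suffix), `hidden_rel` is `NT x nh` with the hidden-unit
#'   relevance at the readout row, plus the output seed and the absorbed
#'   bias share.
#' @export
lrp_firnn <- function(params, trace, config = lrp_config()) {
  stopifnot(trace$arch == "firnn")
  eps <- config$epsilon
  sd_ <- seed_relevance(trace, config)
  dims <- trace$dims
  out <- lrp_dense(trace$hidden, params$W2, sd_$output_rel,
    bias = params$b2, epsilon = eps, bias_sign = 1
  )
  R_h <- out$relevance
  bias_abs <- out$bias_absorbed
  n_t <- nrow(trace$x)
  nd <- dims$nd
  # xtap[i, j] = x_i(n - j + 1) at readout n = NT
  x_suffix <- trace$x[(n_t - nd + 1):n_t, , drop = FALSE]
  xtap <- t(x_suffix[nd:1, , drop = FALSE])
  M <- matrix(0, dims$ni, nd)
  for (h in seq_len(dims$nh)) {
    f <- R_h[h] / stab(trace$pre_h[h], eps)
    M <- M + matrix(params$W1[, , h], dims$ni, nd) * xtap * f
    bias_abs <- bias_abs + (-params$b1[h]) * f
  }
  input_rel <- matrix(0, n_t, dims$ni)
  input_rel[(n_t - nd + 1):n_t, ] <- t(M)[rev(seq_len(nd)), , drop = FALSE]
  hidden_rel <- matrix(0, n_t, dims$nh)
  hidden_rel[n_t, ] <- R_h
  new_relevance_map(
    "firnn", input_rel, hidden_rel, sd_$output_rel, bias_abs,
    sd_$k, config
  )
}

#' Relevance propagation through LSTM/GRU traces
#'
#' Unrolls the epsilon rule backward through the gated recurrence. Under
#' the default signal-takes-all policy, multiplicative gate factors pass
#' relevance entirely to the signal operand (cell / candidate path) and the
#' gates receive none; additive junctions (the cell update and the GRU
#' convex combination) split relevance in proportion to each addend's
#' contribution with epsilon stabilization. Affine (candidate) layers
#' redistribute to the step input and the previous hidden state; biases are
#' absorbed and accounted.
#'
#' @param params LSTM or GRU parameters.
#' @param trace The matching forward trace.
#' @param config An [lrp_config()].
#' @return A `har_relevance` map: `input_rel` (`NT x 6`, signed) and
#'   `hidden_rel` (`NT x nh`, relevance arriving at each step's hidden
#'   state).
#' @export
lrp_gated <- function(params, trace, config = lrp_config()) {
  if (!trace$arch %in% c("lstm", "gru")) abort("trace is not from a gated network.")
  eps <- config$epsilon
  prop <- config$gate_policy == "proportional"
  sd_ <- seed_relevance(trace, config)
  dims <- trace$dims
  nd <- dims$nd
  nh <- dims$nh
  n_t <- nrow(trace$x)
  rows <- trace$rows
  x_suffix <- trace$x[rows, , drop = FALSE]
  H_final <- if (trace$arch == "lstm") trace$H[nd, ] else trace$H[nd, ]
  out <- lrp_dense(as.numeric(H_final), params$W2, sd_$output_rel,
    bias = params$b2, epsilon = eps, bias_sign = 1
  )
  R_h <- out$relevance
  bias_abs <- out$bias_absorbed
  input_rel <- matrix(0, n_t, dims$ni)
  hidden_rel <- matrix(0, n_t, nh)
  row_of <- function(t) rows[t]

  if (trace$arch == "lstm") {
    Rc_carry <- numeric(nh)
    for (t in nd:1) {
      hidden_rel[row_of(t), ] <- hidden_rel[row_of(t), ] + R_h
      x_t <- x_suffix[t, ]
      H_prev <- if (t > 1) trace$H[t - 1, ] else numeric(nh)
      C_prev <- if (t > 1) trace$C[t - 1, ] else numeric(nh)
      gI <- trace$I[t, ]; gF <- trace$F[t, ]; gO <- trace$O[t, ]; gG <- trace$G[t, ]
      C_t <- trace$C[t, ]
      # h_t = o * tanh(c_t)
      if (prop) {
        sp <- split_product(R_h, gO, tanh(C_t))
        R_gate_o <- sp$first
        Rc <- Rc_carry + sp$second
      } else {
        R_gate_o <- numeric(nh)
        Rc <- Rc_carry + R_h
      }
      # c_t = f*c_{t-1} + i*g
      z1 <- gF * C_prev
      z2 <- gI * gG
      f_c <- Rc / stab(C_t, eps)
      R_z1 <- z1 * f_c
      R_z2 <- z2 * f_c
      if (prop) {
        sp1 <- split_product(R_z1, gF, C_prev)
        sp2 <- split_product(R_z2, gI, gG)
        R_gate_f <- sp1$first; Rc_carry <- sp1$second
        R_gate_i <- sp2$first; Rg <- sp2$second
      } else {
        R_gate_f <- R_gate_i <- numeric(nh)
        Rc_carry <- R_z1
        Rg <- R_z2
      }
      # candidate affine
      cand <- affine_redistribute(
        Rg, params$Wx_C, x_t, params$Wh_C, H_prev,
        params$b_C, trace$pre_G[t, ], eps
      )
      input_rel[row_of(t), ] <- input_rel[row_of(t), ] + cand$input
      R_h <- cand$hidden
      bias_abs <- bias_abs + cand$bias
      if (prop) {
        for (gate in list(
          list(R_gate_i, "I", trace$pre_I[t, ]),
          list(R_gate_f, "F", trace$pre_F[t, ]),
          list(R_gate_o, "O", trace$pre_O[t, ])
        )) {
          gr <- affine_redistribute(
            gate[[1]], params[[paste0("Wx_", gate[[2]])]], x_t,
            params[[paste0("Wh_", gate[[2]])]], H_prev,
            params[[paste0("b_", gate[[2]])]], gate[[3]], eps
          )
          input_rel[row_of(t), ] <- input_rel[row_of(t), ] + gr$input
          R_h <- R_h + gr$hidden
          bias_abs <- bias_abs + gr$bias
        }
      }
    }
  } else { # gru
    for (t in nd:1) {
      hidden_rel[row_of(t), ] <- hidden_rel[row_of(t), ] + R_h
      x_t <- x_suffix[t, ]
      H_prev <- if (t > 1) trace$H[t - 1, ] else numeric(nh)
      gU <- trace$U[t, ]; gR <- trace$R[t, ]; gG <- trace$G[t, ]
      H_t <- trace$H[t, ]
      # h_t = u*h_{t-1} + (1-u)*g
      z1 <- gU * H_prev
      z2 <- (1 - gU) * gG
      f_h <- R_h / stab(H_t, eps)
      R_z1 <- z1 * f_h
      R_z2 <- z2 * f_h
      if (prop) {
        sp1 <- split_product(R_z1, gU, H_prev)
        sp2 <- split_product(R_z2, 1 - gU, gG)
        R_gate_u <- sp1$first + sp2$first
        Rh_prev <- sp1$second
        Rg <- sp2$second
      } else {
        R_gate_u <- numeric(nh)
        Rh_prev <- R_z1
        Rg <- R_z2
      }
      # candidate affine; recurrent operand is r * h_{t-1}
      hrec <- gR * H_prev
      R_gate_r <- numeric(nh)
      if (prop) {
        cand_f <- Rg / stab(trace$pre_G[t, ], eps)
        rec_share <- as.numeric(crossprod(params$Wh_C, cand_f)) * hrec
        spr <- split_product(rec_share, gR, H_prev)
        R_gate_r <- spr$first
        cand <- affine_redistribute(
          Rg, params$Wx_C, x_t, params$Wh_C, hrec,
          params$b_C, trace$pre_G[t, ], eps
        )
        cand$hidden <- spr$second
      } else {
        cand <- affine_redistribute(
          Rg, params$Wx_C, x_t, params$Wh_C, hrec,
          params$b_C, trace$pre_G[t, ], eps
        )
      }
      input_rel[row_of(t), ] <- input_rel[row_of(t), ] + cand$input
      bias_abs <- bias_abs + cand$bias
      R_h <- Rh_prev + cand$hidden
      if (prop) {
        for (gate in list(
          list(R_gate_u, "U", trace$pre_U[t, ]),
          list(R_gate_r, "R", trace$pre_R[t, ])
        )) {
          gr <- affine_redistribute(
            gate[[1]], params[[paste0("Wx_", gate[[2]])]], x_t,
            params[[paste0("Wh_", gate[[2]])]], H_prev,
            params[[paste0("b_", gate[[2]])]], gate[[3]], eps
          )
          input_rel[row_of(t), ] <- input_rel[row_of(t), ] + gr$input
          R_h <- R_h + gr$hidden
          bias_abs <- bias_abs + gr$bias
        }
      }
    }
  }
  new_relevance_map(
    trace$arch, input_rel, hidden_rel, sd_$output_rel, bias_abs,
    sd_$k, config
  )
}

#' Relevance map for one window under any architecture
#'
#' @param object A `har_model` or `har_params`.
#' @param window A single window (matrix or one-window tibble slice).
#' @param config An [lrp_config()].
#' @return A `har_relevance` map.
#' @export
lrp_relevance <- function(object, window, config = lrp_config()) {
  params <- if (inherits(object, "har_model")) object$params else object
  trace <- forward_trace(params, window)
  if (attr(params, "arch") == "firnn") {
    lrp_firnn(params, trace, config)
  } else {
    lrp_gated(params, trace, config)
  }
}

#' Relevance maps for every window of a dataset
#'
#' @param model A `har_model`.
#' @param data Dataset tibble (typically the z-scored test partition).
#' @param config An [lrp_config()].
#' @return List with `maps` (one `har_relevance` per window, named by
#'   window id) and `predictions` (tibble of window_id, truth, predicted).
#' @export
lrp_dataset <- function(model, data, config = lrp_config()) {
  arr <- as_window_array(data)
  preds <- predict(model, data)
  n_t <- arr$n_t
  maps <- purrr::map(seq_along(arr$ids), function(s) {
    x <- matrix(arr$X[s, , ], n_t, 6)
    m <- lrp_relevance(model, x, config)
    m$window_id <- arr$ids[s]
    m
  })
  names(maps) <- arr$ids
  list(maps = maps, predictions = preds)
}

#' Temporal normalization of a relevance map
#'
#' Divides the absolute relevance of every (unit, time) cell by the total
#' absolute relevance of the chosen layer, so all cells sum to 1 and maps
#' are comparable across windows, classes and architectures.
#'
#' @param map A `har_relevance`.
#' @param layer `"input"` (channels) or `"hidden"` (hidden units).
#' @return A `NT x n_units` matrix of non-negative weights summing to 1,
#'   with attribute `layer`.
#' @export
normalize_temporal <- function(map, layer = c("input", "hidden")) {
  layer <- match.arg(layer)
  R <- if (layer == "input") map$input_rel else map$hidden_rel
  total <- sum(abs(R))
  if (total == 0) abort("degenerate relevance map: all relevance is zero.")
  out <- abs(R) / total
  attr(out, "layer") <- layer
  out
}

#' Global (per-unit) normalization of a relevance map
#'
#' Sums absolute relevance over time and normalizes across units: the
#' share of total relevance each input channel (or hidden unit) receives
#' over the whole window.
#'
#' @inheritParams normalize_temporal
#' @return Named non-negative vector summing to 1.
#' @export
normalize_global <- function(map, layer = c("input", "hidden")) {
  colSums(normalize_temporal(map, layer))
}

#' Class-wise mean of global relevance vectors
#'
#' Averages the global relevance of correctly classified samples within
#' each class and re-normalizes each class column to sum to 1.
#'
#' @param v_list List of [normalize_global()] vectors, one per sample.
#' @param labels True class ids, same length.
#' @param predictions Predicted class ids, same length.
#' @return A `n_units x n_classes` matrix; every column sums to 1. Classes
#'   without a correct prediction are dropped with a warning.
#' @export
classwise_mean_relevance <- function(v_list, labels, predictions) {
  stopifnot(length(v_list) == length(labels), length(labels) == length(predictions))
  correct <- labels == predictions
  classes <- sort(unique(labels))
  cols <- list()
  for (k in classes) {
    idx <- which(correct & labels == k)
    if (length(idx) == 0) {
      warn(sprintf("class %d has no correctly classified samples; excluded.", k))
      next
    }
    v <- Reduce(`+`, v_list[idx]) / length(idx)
    cols[[as.character(k)]] <- v / sum(v)
  }
  if (length(cols) == 0) abort("no class has a correctly classified sample.")
  out <- do.call(cbind, cols)
  rownames(out) <- names(v_list[[1]])
  out
}

#' @export
tidy.har_relevance <- function(x, layer = c("input", "hidden"), ...) {
  layer <- match.arg(layer)
  R <- if (layer == "input") x$input_rel else x$hidden_rel
  unit <- if (layer == "input") {
    colnames(R) %||% paste0("x", seq_len(ncol(R)))
  } else {
    paste0("h", seq_len(ncol(R)))
  }
  as_tibble(R, .name_repair = ~unit) %>%
    dplyr::mutate(t_index = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"t_index", names_to = "unit", values_to = "relevance")
}
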