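#' Closed-form computational complexity of one architecture
#'
#' Counts, per forward recall, the binary additions (`n_add`), binary
#' multiplications (`n_mul`) and activation-function evaluations (`n_act`)
#' of a dimensioned network, plus its trainable weight count (`n_weights`).
#'
#' Formulas (NI inputs, ND delays, NH hidden units, NC classes):
#' \describe{
#'   \item{FIRNN}{`n_add = n_mul = NI*ND + NI*NH + NH`; `n_act = NH + 1`;
#'     `n_weights = NH*(NI*ND + 1) + NC*(NH + 1)`.}
#'   \item{GRU}{`n_add = 3*NH*ND*(NI + ND) + ND`;
#'     `n_mul = 3*NI*NH*(NI + ND*NH)`; `n_act = 4*ND*NH + 1`;
#'     `n_weights = 3*NH*(NI + NH + 1) + NC*(NH + 1)`.}
#'   \item{LSTM}{`n_add = 4*NH*ND*(NI + ND) + ND`;
#'     `n_mul = 4*NI*NH*(NI + ND*NH)` (the four-gate analogue of the GRU
#'     multiplication count); `n_act = 6*ND*NH + 1`;
#'     `n_weights = 4*NH*(NI + NH + 1) + NC*(NH + 1)`.}
#' }
#'
#' The LSTM multiplication count follows the structural analogy with the
#' GRU row (gate prefactor 4 instead of 3), which is the only form
#' consistent with the weight-count column; see the methods vignette.
#' The weight counts are verified at run time against [init_params()] in
#' the test suite.
#'
#' @param arch One of `"firnn"`, `"lstm"`, `"gru"`.
#' @param dims An [arch_dims()].
#' @return One-row tibble: arch, ni, nd, nh, nc, n_add, n_mul, n_act,
#'   n_weights.
#' @export
#' @examples
#' complexity_profile("firnn", arch_dims(nd = 100, nh = 10))
complexity_profile <- function(arch, dims) {
  arch <- match.arg(arch, har_architectures)
  if (!inherits(dims, "arch_dims")) abort("`dims` must be an arch_dims.")
  ni <- dims$ni; nd <- dims$nd; nh <- dims$nh; nc <- dims$nc
  vals <- switch(arch,
    firnn = list(
      n_add = ni * nd + ni * nh + nh,
      n_mul = ni * nd + ni * nh + nh,
      n_act = nh + 1,
      n_weights = nh * (ni * nd + 1) + nc * (nh + 1)
    ),
    gru = list(
      n_add = 3 * nh * nd * (ni + nd) + nd,
      n_mul = 3 * ni * nh * (ni + nd * nh),
      n_act = 4 * nd * nh + 1,
      n_weights = 3 * nh * (ni + nh + 1) + nc * (nh + 1)
    ),
    lstm = list(
      n_add = 4 * nh * nd * (ni + nd) + nd,
      n_mul = 4 * ni * nh * (ni + nd * nh),
      n_act = 6 * nd * nh + 1,
      n_weights = 4 * nh * (ni + nh + 1) + nc * (nh + 1)
    )
  )
  tibble(
    arch = arch, ni = ni, nd = nd, nh = nh, nc = nc,
    n_add = vals$n_add, n_mul = vals$n_mul, n_act = vals$n_act,
    n_weights = vals$n_weights
  )
}

#' Complexity report over architectures and dimension sets
#'
#' One row per (architecture, dimension set); within each dimension set the
#' per-column minima are flagged, mirroring how complexity tables highlight
#' the cheapest architecture per metric.
#'
#' @param archs Character vector of architectures.
#' @param dims_list A single [arch_dims()] or a list of them.
#' @return Tibble with the profile columns plus logical `min_add`,
#'   `min_mul`, `min_act`, `min_weights` flags.
#' @export
complexity_table <- function(archs = c("firnn", "gru", "lstm"),
                             dims_list = list(arch_dims(nd = 100, nh = 10))) {
  if (inherits(dims_list, "arch_dims")) dims_list <- list(dims_list)
  if (length(archs) == 0 || length(dims_list) == 0) abort("`archs` and `dims_list` must be non-empty.")
  rows <- purrr::map(seq_along(dims_list), function(k) {
    purrr::map(archs, complexity_profile, dims = dims_list[[k]]) %>%
      dplyr::bind_rows() %>%
      dplyr::mutate(dims_set = k)
  }) %>% dplyr::bind_rows()
  rows %>%
    dplyr::group_by(.data$dims_set) %>%
    dplyr::mutate(
      min_add = .data$n_add == min(.data$n_add),
      min_mul = .data$n_mul == min(.data$n_mul),
      min_act = .data$n_act == min(.data$n_act),
      min_weights = .data$n_weights == min(.data$n_weights)
    ) %>%
    dplyr::ungroup()
}
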