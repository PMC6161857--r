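#' Two-step synaptic normalisation of a weight block
#'
#' Presynaptic step: every column (a neuron's efferent weights) is divided by
#' its sum. Postsynaptic step: every row (a neuron's afferent weights) is then
#' divided by its sum, so that each neuron's total synaptic input is exactly 1
#' and its total output is approximately conserved. All-zero columns or rows
#' are left unchanged so that fully silenced synapses never produce NaN.
#'
#' @param block A non-negative numeric matrix.
#' @return The normalised matrix: every row with a nonzero sum sums to 1.
#' @examples
#' m <- matrix(c(0, 0.25, 0.5, 0), 2, 2)
#' normalize_block(m)
#' @export
normalize_block <- function(block) {
  stopifnot(is.matrix(block), all(block >= 0))
  cs <- colSums(block)
  nz <- cs > 0
  block[, nz] <- sweep(block[, nz, drop = FALSE], 2, cs[nz], "/")
  rs <- rowSums(block)
  nz <- rs > 0
  block[nz, ] <- sweep(block[nz, , drop = FALSE], 1, rs[nz], "/")
  block
}

#' Initialise the synaptic weight matrix
#'
#' All four blocks (EE, EI, IE, II) are sampled i.i.d. from U(0, 1); autapses
#' are forbidden, so the EE and II diagonals are zeroed. Each block is then
#' passed through the two-step normalisation. In the spatial variant the
#' Gaussian distance cap is applied to the EE block before normalising.
#'
#' @param params A [sim_params()] object.
#' @return A `weight_matrix` object: a list with matrices `ee` (`n_e` x
#'   `n_e`), `ei` (`n_e` x `n_i`), `ie` (`n_i` x `n_e`), `ii` (`n_i` x `n_i`).
#' @examples
#' set.seed(1)
#' w <- init_weights(sim_params())
#' range(rowSums(w$ee))  # all 1
#' @export
init_weights <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  ne <- params$n_e; ni <- params$n_i
  ee <- matrix(stats::runif(ne * ne), ne, ne); diag(ee) <- 0
  ei <- matrix(stats::runif(ne * ni), ne, ni)
  ie <- matrix(stats::runif(ni * ne), ni, ne)
  ii <- matrix(stats::runif(ni * ni), ni, ni); diag(ii) <- 0
  if (params$spatial) {
    layout <- spatial_layout(params$grid_side)
    ee <- distance_cap(ee, layout, params$a, params$kappa)
  }
  weight_matrix(normalize_block(ee), normalize_block(ei),
                normalize_block(ie), normalize_block(ii))
}

#' Construct a weight matrix object from its four synaptic blocks
#'
#' @param ee,ei,ie,ii Non-negative matrices with entries in `[0, 1]`;
#'   `ee` and `ii` must be square with zero diagonals.
#' @return A `weight_matrix` object.
#' @export
weight_matrix <- function(ee, ei, ie, ii) {
  ne <- nrow(ee); ni <- nrow(ii)
  stopifnot(ncol(ee) == ne, ncol(ii) == ni,
            nrow(ei) == ne, ncol(ei) == ni,
            nrow(ie) == ni, ncol(ie) == ne)
  for (b in list(ee, ei, ie, ii))
    if (any(b < 0) || any(b > 1)) stop("weights must lie in [0, 1]")
  if (any(diag(ee) != 0) || any(diag(ii) != 0))
    stop("autapses are not allowed: ee and ii diagonals must be zero")
  structure(list(ee = ee, ei = ei, ie = ie, ii = ii),
            class = "weight_matrix")
}

#' @exportS3Method print weight_matrix
print.weight_matrix <- function(x, ...) {
  cat("<weight_matrix>", nrow(x$ee), "E /", nrow(x$ii), "I neurons;",
      "mean EE weight", signif(mean(x$ee), 3), "\n")
  invisible(x)
}
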