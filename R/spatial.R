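#' Square-grid layout for the excitatory population
#'
#' Maps excitatory neuron `i` (1-based) to integer coordinates on a
#' `grid_side` x `grid_side` lattice, row-major: neuron `i` sits at
#' `((i-1) %% grid_side, (i-1) %/% grid_side)`.
#'
#' @param grid_side Side length of the square grid.
#' @return A `spatial_layout` object with an integer coordinate matrix
#'   `coords` (`grid_side^2` rows, columns `x`, `y`, 0-based) and `grid_side`.
#' @export
spatial_layout <- function(grid_side) {
  grid_side <- as.integer(grid_side)
  stopifnot(grid_side >= 1L)
  idx <- 0:(grid_side^2 - 1L)
  structure(list(coords = cbind(x = idx %% grid_side, y = idx %/% grid_side),
                 grid_side = grid_side),
            class = "spatial_layout")
}

#' Toroidal (periodic-boundary) distance between two grid neurons
#'
#' Euclidean distance with per-axis wraparound:
#' `delta = min(|d|, grid_side - |d|)` on each axis.
#'
#' @param layout A [spatial_layout()].
#' @param i,j 1-based excitatory neuron indices (vectorised).
#' @return Numeric distance(s).
#' @examples
#' ly <- spatial_layout(32)
#' toroidal_distance(ly, 1, 32)  # (0,0) to (31,0): wraps to 1
#' @export
toroidal_distance <- function(layout, i, j) {
  stopifnot(inherits(layout, "spatial_layout"))
  ci <- layout$coords[i, , drop = FALSE]
  cj <- layout$coords[j, , drop = FALSE]
  if (nrow(ci) == 1L && nrow(cj) > 1L) ci <- ci[rep(1L, nrow(cj)), ]
  if (nrow(cj) == 1L && nrow(ci) > 1L) cj <- cj[rep(1L, nrow(ci)), ]
  d <- abs(ci - cj)
  d <- pmin(d, layout$grid_side - d)
  sqrt(rowSums(d^2))
}

#' Gaussian cap on distance-dependent connection strength
#'
#' Clamps every EE entry to the maximum strength
#' `w_max(d) = a * exp(-d^2 / (2 * kappa^2))`, where `d` is the toroidal
#' distance between the two neurons. Applied after normalisation each step in
#' the spatial variant, so capped rows may sum to less than 1.
#'
#' @param w_ee Square EE weight matrix over the grid population.
#' @param layout A [spatial_layout()] with `grid_side^2 == nrow(w_ee)`.
#' @param a Cap amplitude.
#' @param kappa Cap width in grid units.
#' @return The capped matrix.
#' @export
distance_cap <- function(w_ee, layout, a, kappa) {
  pmin(w_ee, distance_cap_matrix(layout, a, kappa))
}

#' Matrix of pairwise Gaussian connection-strength caps
#'
#' @inheritParams distance_cap
#' @return A `grid_side^2` square matrix of `w_max(d_ij)` values.
#' @export
distance_cap_matrix <- function(layout, a, kappa) {
  stopifnot(inherits(layout, "spatial_layout"))
  n <- nrow(layout$coords)
  dx <- abs(outer(layout$coords[, "x"], layout$coords[, "x"], "-"))
  dy <- abs(outer(layout$coords[, "y"], layout$coords[, "y"], "-"))
  dx <- pmin(dx, layout$grid_side - dx)
  dy <- pmin(dy, layout$grid_side - dy)
  a * exp(-(dx^2 + dy^2) / (2 * kappa^2))
}
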