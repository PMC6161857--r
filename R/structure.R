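#' Symmetrise a directed weight matrix
#'
#' Community detection operates on the symmetrised matrix
#' `w~ = w + t(w)`. The plasticity rule acts symmetrically and the two-step
#' normalisation distributes weight both pre- and postsynaptically, so mature
#' EE matrices are already close to symmetric and this loses little structure.
#'
#' @param ee A square matrix.
#' @return `ee + t(ee)`.
#' @export
symmetrize <- function(ee) {
  stopifnot(is.matrix(ee), nrow(ee) == ncol(ee))
  ee + t(ee)
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity of a symmetric non-negative weight matrix under a
#' given partition: with `S = sum(w)` (every ordered pair counted) and node
#' strengths `k_i = rowSums(w)`,
#' `Q = (1/S) * sum_{ij in same cluster} (w_ij - k_i * k_j / S)`.
#' On `k` disconnected communities of equal total weight this gives
#' `Q = 1 - 1/k`. `variant = "methods"` selects an alternative normalisation
#' with an extra factor of 2 in both the prefactor and the null model
#' (yielding `1/2 - 1/(4k)` on the same case); the standard convention is the
#' default as it matches the usual Louvain implementations.
#'
#' @param w A symmetric non-negative matrix (symmetrise directed input with
#'   [symmetrize()] first).
#' @param partition A partition-valued [assembly_set()] or a membership
#'   vector.
#' @param variant `"standard"` (default) or `"methods"`.
#' @return The modularity Q (at most 1).
#' @examples
#' w <- as.matrix(Matrix::bdiag(matrix(1, 2, 2), matrix(1, 2, 2)))
#' modularity_q(w, c(1, 1, 2, 2))  # 1 - 1/2 = 0.5
#' @export
modularity_q <- function(w, partition, variant = c("standard", "methods")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  m <- if (inherits(partition, "assembly_set")) {
    if (partition$source == "ica")
      stop("modularity requires a true partition, not an overlapping cover")
    as_membership(partition)
  } else as.integer(partition)
  stopifnot(length(m) == nrow(w))
  s <- sum(w)
  if (s == 0) stop("weight matrix has zero total weight")
  k <- rowSums(w)
  denom <- if (variant == "standard") s else 2 * s
  same <- outer(m, m, "==")
  sum((w - outer(k, k) / denom)[same]) / denom
}

#' Detect assemblies from the synaptic weight matrix
#'
#' Symmetrises the EE block and runs Louvain greedy modularity maximisation
#' with several random node orders (restarts), keeping the partition with the
#' highest modularity. Deterministic given the seed.
#'
#' @param ee Non-negative EE weight matrix.
#' @param restarts Number of random-restart Louvain runs.
#' @param seed Optional integer seed.
#' @return A partition-valued [assembly_set()] with `source = "louvain"`,
#'   ordered by first member; the winning modularity is attached as attribute
#'   `"Q"`.
#' @export
detect_assemblies_weights <- function(ee, restarts = 10, seed = NULL) {
  stopifnot(is.matrix(ee), nrow(ee) == ncol(ee), nrow(ee) >= 1, all(ee >= 0))
  if (!is.null(seed)) set.seed(seed)
  w <- symmetrize(ee)
  n <- nrow(w)
  best_q <- -Inf; best_m <- rep(1L, n)
  for (r in seq_len(restarts)) {
    perm <- sample.int(n)
    g <- igraph::graph_from_adjacency_matrix(w[perm, perm, drop = FALSE],
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mem <- integer(n)
    mem[perm] <- as.integer(igraph::membership(igraph::cluster_louvain(g)))
    q <- modularity_q(w, mem)
    if (q > best_q) { best_q <- q; best_m <- mem }
  }
  # relabel communities by their first member for a permutation-equivariant
  # canonical form
  first <- vapply(split(seq_len(n), best_m), min, integer(1))
  relabel <- rank(first)
  aset <- membership_to_assembly_set(relabel[match(best_m, names(first))],
                                     source = "louvain")
  attr(aset, "Q") <- best_q
  aset
}

#' Eigenvalue gap below the leading community eigenvalues
#'
#' Eigenvalues of the raw (non-symmetrised) EE matrix are sorted by
#' descending real part (ties broken by descending imaginary part) and the gap
#' `delta_lambda = Re(lambda_k) - Re(lambda_(k+1))` is returned. When `k`
#' communities are strongly embedded, `k` eigenvalues detach from the spectral
#' band and the gap grows.
#'
#' @param ee Square EE weight matrix.
#' @param k Number of assemblies (as estimated by
#'   [detect_assemblies_weights()]).
#' @return The eigengap (non-negative for real-dominant spectra).
#' @export
eigengap <- function(ee, k) {
  stopifnot(is.matrix(ee), nrow(ee) == ncol(ee))
  n <- nrow(ee)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  ev <- eigen(ee, only.values = TRUE)$values
  ord <- order(-Re(ev), -Im(ev))
  ev <- ev[ord]
  Re(ev[k]) - Re(ev[k + 1])
}

#' Coefficient of variation of assembly sizes
#'
#' Sample standard deviation of the assembly sizes divided by their mean.
#' Near 0 for homogeneous sizes, near 1 for highly dispersed sizes.
#'
#' @param partition An [assembly_set()] with at least two assemblies.
#' @return The CV (non-negative).
#' @export
assembly_size_cv <- function(partition) {
  stopifnot(inherits(partition, "assembly_set"))
  sizes <- lengths(partition$assemblies)
  if (length(sizes) < 2) stop("CV requires at least two assemblies")
  stats::sd(sizes) / mean(sizes)
}

#' Mean within-assembly synaptic weight
#'
#' Mean of the off-diagonal EE entries whose pre- and postsynaptic neurons
#' belong to the same assembly.
#'
#' @param ee EE weight matrix.
#' @param partition A partition-valued [assembly_set()].
#' @return The mean within-assembly weight.
#' @export
mean_within_assembly_weight <- function(ee, partition) {
  m <- as_membership(partition)
  stopifnot(length(m) == nrow(ee))
  same <- outer(m, m, "==")
  diag(same) <- FALSE
  mean(ee[same])
}

#' Pairwise co-membership counts across assembly samples
#'
#' Entry (i, j) counts the samples in which neurons i and j were assigned to
#' the same assembly; the diagonal is zeroed for reporting.
#'
#' @param samples A list of [assembly_set()] objects over the same population.
#' @return An integer count matrix.
#' @export
co_membership <- function(samples) {
  stopifnot(length(samples) >= 1)
  n <- samples[[1]]$n_neurons
  counts <- matrix(0L, n, n)
  for (s in samples) {
    stopifnot(inherits(s, "assembly_set"), s$n_neurons == n)
    for (a in s$assemblies) counts[a, a] <- counts[a, a] + 1L
  }
  diag(counts) <- 0L
  counts
}

#' Structural metrics of a weight matrix
#'
#' Convenience wrapper computing the modularity, assembly count, eigengap,
#' mean within-assembly weight and assembly-size CV from an EE matrix in one
#' call.
#'
#' @param ee EE weight matrix.
#' @param restarts,seed Passed to [detect_assemblies_weights()].
#' @return A one-row data.frame with columns `q`, `n_assemblies`,
#'   `delta_lambda`, `mean_within_weight`, `size_cv`.
#' @export
structural_metrics <- function(ee, restarts = 10, seed = NULL) {
  aset <- detect_assemblies_weights(ee, restarts = restarts, seed = seed)
  k <- length(aset)
  data.frame(
    q = attr(aset, "Q"),
    n_assemblies = k,
    delta_lambda = if (k >= 1 && k < nrow(ee)) eigengap(ee, k) else NA_real_,
    mean_within_weight = mean_within_assembly_weight(ee, aset),
    size_cv = if (k >= 2) assembly_size_cv(aset) else NA_real_)
}
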