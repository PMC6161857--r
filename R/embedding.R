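#' Embed artificial assemblies into an EE weight matrix
#'
#' Partitions `n_e` excitatory neurons into `k` clusters of (near-)equal size
#' and samples within-cluster weights from U(0, 1) and between-cluster weights
#' from U(0, 1 - alpha), so the separation parameter `alpha` controls how
#' strongly the assemblies are embedded: `alpha = 0` gives an unstructured
#' matrix, `alpha = 1` gives `k` disconnected blocks. The matrix is then
#' passed through the two-step normalisation. When `k` does not divide `n_e`,
#' the first `n_e %% k` clusters get one extra member.
#'
#' @param n_e Number of excitatory neurons.
#' @param k Number of assemblies to embed (`1 <= k <= n_e`).
#' @param alpha Separation parameter in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with the normalised `ee` matrix and `truth`, the ground-
#'   truth partition as an [assembly_set()] with `source = "truth"`.
#' @examples
#' emb <- embed_assemblies(100, k = 5, alpha = 0.9, seed = 1)
#' lengths(emb$truth$assemblies)
#' @export
embed_assemblies <- function(n_e, k, alpha, seed = NULL) {
  n_e <- as.integer(n_e); k <- as.integer(k)
  if (k < 1L || k > n_e) stop("k must satisfy 1 <= k <= n_e")
  stopifnot(alpha >= 0, alpha <= 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n_e %/% k, k) + c(rep(1L, n_e %% k), rep(0L, k - n_e %% k))
  memb <- rep(seq_len(k), sizes)
  ee <- matrix(stats::runif(n_e * n_e), n_e, n_e)
  between <- outer(memb, memb, "!=")
  ee[between] <- ee[between] * (1 - alpha)
  diag(ee) <- 0
  list(ee = normalize_block(ee),
       truth = membership_to_assembly_set(memb, source = "truth"))
}
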