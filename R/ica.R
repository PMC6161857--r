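#' Detect assemblies from an activity raster by independent component analysis
#'
#' The standard activity-based assembly detector: each neuron's trace is
#' z-scored; the number of assemblies `k` is estimated as the number of
#' eigenvalues of the neuron correlation matrix exceeding the Marchenko-Pastur
#' upper bound `(1 + sqrt(n/T))^2` (the largest eigenvalue expected from
#' independent traces); the data are projected onto the `k` leading principal
#' components and whitened; FastICA (symmetric decorrelation, logcosh
#' contrast) extracts `k` independent components; each component's assembly is
#' the set of neurons whose loading magnitude exceeds two standard deviations
#' of that component's loadings, with the component sign aligned so its
#' largest-magnitude loading is positive.
#'
#' @param raster A binary (or z-scorable) [activity_raster()] or matrix,
#'   neurons x timesteps, with `T` much larger than `n`.
#' @param seed Optional integer seed (ICA initialisation is random).
#' @param max_iter,tol FastICA iteration controls.
#' @return An [assembly_set()] with `source = "ica"` (possibly empty when no
#'   eigenvalue clears the Marchenko-Pastur bound); the estimated component
#'   count is attached as attribute `"k_hat"` and the neuron-space loading
#'   matrix as `"loadings"`.
#' @export
ica_detect_assemblies <- function(raster, seed = NULL, max_iter = 200,
                                  tol = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  v <- as_raster_values(raster)
  n <- nrow(v); t_len <- ncol(v)
  if (t_len <= n)
    warning("raster has fewer timesteps than neurons; ",
            "the Marchenko-Pastur bound is unreliable")
  sds <- apply(v, 1, stats::sd)
  active <- sds > 0
  z <- matrix(0, n, t_len)
  z[active, ] <- (v[active, , drop = FALSE] - rowMeans(
    v[active, , drop = FALSE])) / sds[active]
  corr <- tcrossprod(z) / t_len
  eig <- eigen(corr, symmetric = TRUE)
  mp_upper <- (1 + sqrt(n / t_len))^2
  k_hat <- sum(eig$values > mp_upper)
  if (k_hat == 0) {
    out <- assembly_set(list(), n, source = "ica")
    attr(out, "k_hat") <- 0L
    return(out)
  }
  # whiten: project onto the k leading PCs, unit variance per component
  vecs <- eig$vectors[, seq_len(k_hat), drop = FALSE]
  vals <- eig$values[seq_len(k_hat)]
  y <- diag(1 / sqrt(vals), k_hat) %*% t(vecs) %*% z
  w_unmix <- fastica_symmetric(y, max_iter = max_iter, tol = tol)
  # neuron-space loadings of each independent component
  loadings <- vecs %*% diag(sqrt(vals), k_hat) %*% t(w_unmix)
  assemblies <- vector("list", k_hat)
  for (c_i in seq_len(k_hat)) {
    l <- loadings[, c_i]
    if (l[which.max(abs(l))] < 0) l <- -l
    loadings[, c_i] <- l
    assemblies[[c_i]] <- which(abs(l) > 2 * stats::sd(l))
  }
  assemblies <- assemblies[lengths(assemblies) > 0]
  out <- assembly_set(assemblies, n, source = "ica")
  attr(out, "k_hat") <- as.integer(k_hat)
  attr(out, "loadings") <- loadings
  out
}

# Symmetric FastICA on whitened data y (components x samples): returns the
# orthonormal unmixing matrix W (components x components) maximising
# logcosh non-gaussianity. Standard fixed-point iteration with symmetric
# decorrelation W <- (W W^T)^{-1/2} W.
fastica_symmetric <- function(y, max_iter = 200, tol = 1e-6) {
  k <- nrow(y); t_len <- ncol(y)
  sym_decorrelate <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% w
  }
  w <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    wy <- w %*% y
    g <- tanh(wy)
    g_prime <- rowMeans(1 - g^2)
    w_new <- g %*% t(y) / t_len - diag(g_prime, k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(1 - abs(rowSums(w_new * w))))
    w <- w_new
    if (delta < tol) break
  }
  w
}
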