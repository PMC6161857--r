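# Independent oracles used across test files.

# Enumerate all set partitions of 1..n as membership vectors (restricted
# growth strings). Bell(8) = 4140, fine for n <= 10.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(m, k) {
    i <- length(m) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- m
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) recurse(c(m, lab), max(k, lab))
  }
  recurse(integer(), 0L)
  out
}

# Exhaustive maximum-modularity partition of a small symmetric matrix.
brute_force_modularity <- function(w) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(m) modularity_q(w, m), numeric(1))
  best <- which.max(qs)
  list(q = qs[best], membership = parts[[best]], all_q = qs)
}

# Small directed weighted toy graph with two noisy planted communities,
# strong enough that greedy modularity maximisation can reach the global
# optimum but with fully random weights.
toy_community_graph <- function(seed, n = 8) {
  set.seed(seed)
  m <- rep(1:2, each = n / 2)
  w <- matrix(stats::runif(n * n, 0, 0.4), n, n)
  same <- outer(m, m, "==")
  w[same] <- stats::runif(sum(same), 0.6, 1)
  diag(w) <- 0
  w
}

# Block-diagonal matrix of k dense equal-weight communities of size s.
disconnected_communities <- function(k, s, value = 1) {
  blocks <- replicate(k, {
    b <- matrix(value, s, s); diag(b) <- 0; b
  }, simplify = FALSE)
  as.matrix(Matrix::bdiag(blocks))
}
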