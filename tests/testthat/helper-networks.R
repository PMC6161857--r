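# Shared fixtures built once per test run: developing the default network for
# 100,000 steps is the expensive common setup for the dispersion, probe,
# autosimilarity and development-trace checks. Networks are cached per seed so
# different blocks can share them.

.hebbnet_cache <- new.env(parent = emptyenv())

# n default-parameter networks (seeds 101, 102, ...) developed for 100,000
# steps with EE snapshots every 5,000 steps and the final Louvain partition.
mature_networks <- function(n = 10) {
  lapply(seq_len(n), function(s) {
    key <- sprintf("net_%d", s)
    if (is.null(.hebbnet_cache[[key]])) {
      params <- sim_params(seed = 100 + s)
      res <- simulate_network(params, snapshot_every = 5000,
                              record_raster = FALSE)
      aset <- detect_assemblies_weights(res$weights_final$ee, seed = 900 + s)
      .hebbnet_cache[[key]] <- list(params = params, result = res,
                                    assemblies = aset, seed = 100 + s)
    }
    .hebbnet_cache[[key]]
  })
}

# Pooled stimulation-probe fractions (singles, pairs, triples) over the
# cached mature networks: total triggering trials / total trials.
probe_fractions <- function(nets) {
  key <- sprintf("probe_%d", length(nets))
  if (is.null(.hebbnet_cache[[key]])) {
    .hebbnet_cache[[key]] <- vapply(1:3, function(g) {
      trig <- tot <- 0
      for (nt in nets) {
        pr <- stimulation_probe(nt$result$weights_final, nt$params,
                                nt$assemblies, g, seed = nt$seed + 7000)
        trig <- trig + sum(pr$per_assembly$n_triggered)
        tot <- tot + pr$n_trials
      }
      trig / tot
    }, numeric(1))
  }
  .hebbnet_cache[[key]]
}

# Full weight matrix whose EE block carries artificially embedded assemblies
# (other blocks freshly initialised), for fixed-weight activity runs.
embedded_network <- function(n_e, k, alpha, seed) {
  emb <- embed_assemblies(n_e, k, alpha, seed = seed)
  params <- sim_params(n_e = n_e, n_i = n_e / 4, plasticity = FALSE,
                       seed = seed + 1)
  set.seed(seed + 1)
  w <- init_weights(params)
  w$ee <- emb$ee
  list(w = w, truth = emb$truth, params = params)
}
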