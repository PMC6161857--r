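test_that("symmetrisation adds the transpose", {
  m <- matrix(c(0, 0, 1, 0), 2, 2)  # [[0, 1], [0, 0]] by row
  expect_equal(symmetrize(m), matrix(c(0, 1, 1, 0), 2, 2))
  s <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(symmetrize(s), 2 * s)
  set.seed(1)
  r <- matrix(runif(25), 5, 5)
  expect_equal(symmetrize(r) - t(symmetrize(r)), matrix(0, 5, 5))
})

test_that("modularity matches closed forms and the igraph convention", {
  # k disconnected equal communities: Q = 1 - 1/k
  for (k in c(2, 5)) {
    w <- disconnected_communities(k, 4)
    memb <- rep(seq_len(k), each = 4)
    expect_equal(modularity_q(w, memb), 1 - 1 / k)
    # the literal alternative normalisation halves the null and prefactor
    expect_equal(modularity_q(w, memb, variant = "methods"),
                 0.5 - 1 / (4 * k))
  }
  # everything in one cluster: Q = 0
  set.seed(2)
  r <- matrix(runif(36), 6, 6); diag(r) <- 0  # autapse-free, as in the model
  w <- symmetrize(r)
  expect_equal(modularity_q(w, rep(1, 6)), 0)

  # agreement with igraph's weighted modularity on random partitions
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  for (s in 1:5) {
    set.seed(s)
    memb <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(w, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(w, rep(1, 5)), "length|TRUE")
})

test_that("Louvain detection attains the exhaustive optimum on small graphs", {
  # two disjoint 4-cliques
  w <- disconnected_communities(2, 4)
  oracle <- brute_force_modularity(w)
  det <- detect_assemblies_weights(w / 2, seed = 3)  # symmetrize doubles back
  expect_equal(attr(det, "Q"), oracle$q)
  expect_equal(as_membership(det), oracle$membership)
  # no partition beats the exhaustive optimum
  expect_true(all(oracle$all_q <= oracle$q + 1e-12))

  # weighted 8-node toy graph with noisy planted communities
  r <- toy_community_graph(5)
  oracle2 <- brute_force_modularity(symmetrize(r))
  det2 <- detect_assemblies_weights(r, restarts = 20, seed = 6)
  expect_equal(attr(det2, "Q"), oracle2$q, tolerance = 1e-12)
  expect_equal(as_membership(det2), oracle2$membership)
})

test_that("detection is permutation-equivariant on structured input", {
  emb <- embed_assemblies(60, 3, 0.9, seed = 9)
  det <- detect_assemblies_weights(emb$ee, seed = 10)
  set.seed(11)
  perm <- sample(60)
  ee_p <- emb$ee[perm, perm]
  det_p <- detect_assemblies_weights(ee_p, seed = 10)
  # the partition of the relabelled matrix is the relabelled partition:
  # neuron j of the permuted matrix is original neuron perm[j]
  m1 <- as_membership(det)
  m2 <- as_membership(det_p)
  m2_on_orig <- integer(60)
  m2_on_orig[perm] <- m2
  expect_equal(length(unique(paste(m1, m2_on_orig))), length(unique(m1)))
})

test_that("eigengap follows the block spectrum of disconnected cycles", {
  blk <- matrix(c(0, 1, 1, 0), 2, 2)
  ee <- as.matrix(Matrix::bdiag(blk, blk))  # spectrum {1, 1, -1, -1}
  expect_equal(eigengap(ee, 2), 2)
  expect_equal(eigengap(ee, 3), 0)
  expect_error(eigengap(ee, 4), "k must")
  expect_error(eigengap(ee, 0), "k must")
})

test_that("size CV and within-assembly weight match hand arithmetic", {
  aset <- assembly_set(list(1:10, 11:20, 21:30), 30, source = "truth")
  expect_equal(assembly_size_cv(aset), 0)
  aset2 <- assembly_set(list(1:5, 6:15, 16:30), 30, source = "truth")
  expect_equal(assembly_size_cv(aset2), 0.5)  # sd(5,10,15)/10
  expect_error(assembly_size_cv(assembly_set(list(1:30), 30, "truth")),
               "two assemblies")

  ee <- matrix(0.25, 30, 30); diag(ee) <- 0
  expect_equal(mean_within_assembly_weight(ee, aset), 0.25)
  # alpha = 1: between-assembly weights vanish, so the within mean equals the
  # mean over all nonzero entries
  emb <- embed_assemblies(40, 4, 1, seed = 12)
  expect_equal(mean_within_assembly_weight(emb$ee, emb$truth),
               mean(emb$ee[emb$ee > 0]))
})

test_that("co-membership counts repeated and shuffled partitions correctly", {
  aset <- assembly_set(list(1:3, 4:6), 6, source = "truth")
  cm <- co_membership(rep(list(aset), 100))
  expect_equal(cm[1, 2], 100L)
  expect_equal(cm[1, 4], 0L)
  expect_equal(diag(cm), rep(0L, 6))
  # a single sample gives a binary matrix
  expect_true(all(co_membership(list(aset)) %in% 0:1))
})
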