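Package: hebbnet
Title: Self-Organisation of Neural Assemblies in Recurrent Binary Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent network of binary excitatory and inhibitory
    neurons in which spontaneous, noise-driven activity interacts with a
    covariance Hebbian plasticity rule and a two-step (presynaptic then
    postsynaptic) synaptic normalisation to self-organise neural assemblies
    without any structured afferent input. Includes a distance-dependent
    spatial variant on a toroidal grid, generators for weight matrices with
    artificially embedded assemblies, structural analysis of the synaptic
    weight matrix (modularity, Louvain community detection, eigenvalue gap,
    assembly size statistics, co-membership), and activity-based analysis
    (raster binarisation, assembly event detection, ICA assembly extraction
    with a Marchenko-Pastur component count, best-match and autosimilarity
    scoring, exponential decay fits, build-up profiles, and stimulation
    probes of mature networks).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    minpack.lm,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
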