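#' A collection of neuron assemblies
#'
#' An assembly set is a list of neuron-index sets over a population of
#' `n_neurons`, together with its provenance. Sets from Louvain community
#' detection or ground truth are partitions (disjoint, covering); ICA-derived
#' sets may overlap and need not cover the population.
#'
#' @param assemblies List of integer vectors of 1-based neuron indices.
#' @param n_neurons Total population size.
#' @param source One of `"louvain"`, `"ica"`, `"truth"`.
#' @return An `assembly_set` object.
#' @export
assembly_set <- function(assemblies, n_neurons,
                         source = c("louvain", "ica", "truth")) {
  source <- match.arg(source)
  assemblies <- lapply(assemblies, function(a) sort(unique(as.integer(a))))
  idx <- unlist(assemblies)
  if (length(idx) && (any(idx < 1L) || any(idx > n_neurons)))
    stop("assembly indices must lie in [1, n_neurons]")
  if (source %in% c("louvain", "truth") && length(assemblies)) {
    if (length(idx) != n_neurons || anyDuplicated(idx) ||
        length(unique(idx)) != n_neurons)
      stop(source, " assemblies must form a partition of the population")
  }
  structure(list(assemblies = assemblies, n_neurons = as.integer(n_neurons),
                 source = source),
            class = "assembly_set")
}

#' @exportS3Method print assembly_set
print.assembly_set <- function(x, ...) {
  cat("<assembly_set>", length(x$assemblies), "assemblies over",
      x$n_neurons, "neurons (source:", paste0(x$source, ");"),
      "sizes:", paste(lengths(x$assemblies), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method length assembly_set
length.assembly_set <- function(x) length(x$assemblies)

#' Convert an assembly partition to a membership vector
#'
#' @param aset A partition-valued [assembly_set()].
#' @return Integer vector of length `n_neurons`; entry `i` is the index of the
#'   assembly containing neuron `i`.
#' @export
as_membership <- function(aset) {
  stopifnot(inherits(aset, "assembly_set"))
  m <- integer(aset$n_neurons)
  for (k in seq_along(aset$assemblies)) m[aset$assemblies[[k]]] <- k
  if (any(m == 0L)) stop("assembly set does not cover the population")
  m
}

#' Build an assembly set from a membership vector
#'
#' @param membership Integer community labels, one per neuron.
#' @param source Provenance label, as in [assembly_set()].
#' @return An [assembly_set()].
#' @export
membership_to_assembly_set <- function(membership, source = "louvain") {
  assembly_set(split(seq_along(membership), membership),
               n_neurons = length(membership), source = source)
}
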