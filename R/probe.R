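#' Stimulation probe of a mature, frozen network
#'
#' Measures how many neurons must be co-activated to ignite a full assembly
#' event. Plasticity and spontaneous background noise are disabled; for each
#' assembly, every combination of `group_size` members (or a seeded random
#' subsample of at most `max_combinations` combinations) is forced active at
#' `t = 0` and the network is run for `horizon` steps. A trial counts as
#' triggering when the complete assembly (a fraction `completion` of its
#' members, 1 by default) is simultaneously active at some step within the
#' horizon.
#'
#' @param w A [weight_matrix()] (typically the final weights of a
#'   developmental run).
#' @param params The [sim_params()] of the network (only `theta` and the
#'   population sizes are used; plasticity and noise are forced off).
#' @param assemblies A partition-valued [assembly_set()] of the network.
#' @param group_size Number of neurons stimulated per trial (e.g. 1, 2, 3).
#' @param horizon Steps allowed for the assembly to complete.
#' @param completion Fraction of members that must be co-active to count as a
#'   complete activation.
#' @param max_combinations Cap on combinations per assembly (seeded
#'   subsample above this).
#' @param seed Optional integer seed for the subsampling.
#' @return A `probe_result` list: `fraction` (pooled triggering fraction over
#'   all trials), `n_trials`, and `per_assembly` (data.frame with columns
#'   `assembly`, `size`, `n_trials`, `n_triggered`).
#' @export
stimulation_probe <- function(w, params, assemblies, group_size, horizon = 20,
                              completion = 1, max_combinations = 2000,
                              seed = NULL) {
  stopifnot(inherits(w, "weight_matrix"), inherits(params, "sim_params"),
            inherits(assemblies, "assembly_set"),
            group_size >= 0, horizon >= 1, completion > 0, completion <= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- params$theta
  rows <- list()
  for (a_i in seq_along(assemblies$assemblies)) {
    members <- assemblies$assemblies[[a_i]]
    size <- length(members)
    if (group_size > size) {
      warning("assembly ", a_i, " (size ", size,
              ") smaller than group_size; skipped")
      next
    }
    combos <- if (group_size == 0) {
      matrix(integer(0), nrow = 0, ncol = 1)
    } else if (choose(size, group_size) <= max_combinations) {
      utils::combn(members, group_size)
    } else {
      # seeded subsample of distinct combinations
      seen <- new.env(hash = TRUE)
      picks <- matrix(0L, group_size, max_combinations)
      got <- 0L
      while (got < max_combinations) {
        cand <- sort(sample(members, group_size))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          picks[, got] <- cand
        }
      }
      picks
    }
    n_trials <- ncol(combos)
    if (n_trials == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        assembly = a_i, size = size, n_trials = 0L, n_triggered = 0L)
      next
    }
    # batch all trials of this assembly: one state column per combination
    x_e <- matrix(0, params$n_e, n_trials)
    if (group_size > 0)
      x_e[cbind(as.vector(combos),
                rep(seq_len(n_trials), each = group_size))] <- 1
    x_i <- matrix(0, params$n_i, n_trials)
    need <- completion * size
    done <- rep(FALSE, n_trials)
    for (t in seq_len(horizon)) {
      in_e <- w$ee %*% x_e - w$ei %*% x_i
      in_i <- w$ie %*% x_e - w$ii %*% x_i
      x_e <- (in_e - theta > 0) * 1
      x_i <- (in_i - theta > 0) * 1
      done <- done | (colSums(x_e[members, , drop = FALSE]) >= need)
      if (all(done)) break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      assembly = a_i, size = size, n_trials = n_trials,
      n_triggered = sum(done))
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || sum(per$n_trials) == 0)
    return(structure(list(fraction = 0, n_trials = 0L, per_assembly = per),
                     class = "probe_result"))
  structure(list(fraction = sum(per$n_triggered) / sum(per$n_trials),
                 n_trials = sum(per$n_trials), per_assembly = per),
            class = "probe_result")
}

#' @exportS3Method print probe_result
print.probe_result <- function(x, ...) {
  cat("<probe_result>", x$n_trials, "trials,",
      sprintf("%.2f%%", 100 * x$fraction), "triggered\n")
  invisible(x)
}
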