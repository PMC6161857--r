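#' Create an initial network state
#'
#' The network starts silent (all states 0) unless initial states are given;
#' running means are empty at `t = 0` and accumulate from the first step.
#'
#' @param params A [sim_params()] object.
#' @param p Baseline activation probabilities, as returned by
#'   [sample_baseline_rates()]; sampled from the current RNG if `NULL`.
#' @param x_e,x_i Optional initial binary state vectors.
#' @return A `network_state` object with fields `x_e`, `x_i`, `mean_e`,
#'   `mean_i`, `p_e`, `p_i` and the timestep counter `t`.
#' @export
network_state <- function(params, p = NULL, x_e = NULL, x_i = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(p)) p <- sample_baseline_rates(params)
  if (is.null(x_e)) x_e <- numeric(params$n_e)
  if (is.null(x_i)) x_i <- numeric(params$n_i)
  stopifnot(length(x_e) == params$n_e, length(x_i) == params$n_i,
            all(x_e %in% c(0, 1)), all(x_i %in% c(0, 1)))
  structure(list(x_e = as.numeric(x_e), x_i = as.numeric(x_i),
                 mean_e = numeric(params$n_e), mean_i = numeric(params$n_i),
                 p_e = p$p_e, p_i = p$p_i, t = 0L),
            class = "network_state")
}

#' Advance the network one timestep (synchronous threshold update)
#'
#' Every neuron's new state is computed from the previous state vector. A
#' neuron activates iff its net input exceeds the threshold strictly:
#' `x_i(t+1) = 1` iff
#' `sum_j w_ij^(XE) x_j^E - sum_j w_ij^(XI) x_j^I + beta - theta > 0`,
#' where the noise term `beta` equals `1 + theta` with the neuron's baseline
#' probability `p_i` (guaranteeing activation regardless of synaptic input)
#' and 0 otherwise. Noise is drawn in fixed order, excitatory then inhibitory
#' population, so runs are reproducible from the seed.
#'
#' @param state A [network_state()].
#' @param w A [weight_matrix()].
#' @param params A [sim_params()].
#' @return The state after one step, with `t` incremented (running means are
#'   not yet updated; see [update_running_means()]).
#' @export
step_dynamics <- function(state, w, params) {
  stopifnot(inherits(state, "network_state"), inherits(w, "weight_matrix"),
            nrow(w$ee) == length(state$x_e), nrow(w$ii) == length(state$x_i))
  beta_e <- (stats::runif(params$n_e) < state$p_e) * (1 + params$theta)
  beta_i <- (stats::runif(params$n_i) < state$p_i) * (1 + params$theta)
  in_e <- drop(w$ee %*% state$x_e - w$ei %*% state$x_i)
  in_i <- drop(w$ie %*% state$x_e - w$ii %*% state$x_i)
  state$x_e <- as.numeric(in_e + beta_e - params$theta > 0)
  state$x_i <- as.numeric(in_i + beta_i - params$theta > 0)
  state$t <- state$t + 1L
  state
}

#' Fold the current state into the online running means
#'
#' Maintains `<x>_t = ((t - 1) * <x>_{t-1} + x(t)) / t` for every neuron, so
#' that at any time the stored mean equals the arithmetic mean of all states
#' from step 1 to `t`.
#'
#' @param state A [network_state()] whose `x_e`/`x_i` hold the state at the
#'   current timestep `t >= 1`.
#' @return The state with updated `mean_e`, `mean_i`.
#' @export
update_running_means <- function(state) {
  stopifnot(state$t >= 1L)
  t <- state$t
  state$mean_e <- ((t - 1) * state$mean_e + state$x_e) / t
  state$mean_i <- ((t - 1) * state$mean_i + state$x_i) / t
  state
}

#' Covariance Hebbian update of the excitatory weights
#'
#' Adds `eta * (x_i - <x_i>_t) * (x_j - <x_j>_t)` to every off-diagonal EE
#' entry, where the running means include the current state (call
#' [update_running_means()] first). Weights are clamped below at 0 (lower
#' saturation constraint); the diagonal and the EI/IE/II blocks are untouched.
#'
#' @param w A [weight_matrix()].
#' @param state A [network_state()] with means updated through the current
#'   step.
#' @param eta Learning rate.
#' @return The updated weight matrix.
#' @export
covariance_update <- function(w, state, eta) {
  d <- state$x_e - state$mean_e
  ee <- w$ee + eta * tcrossprod(d)
  diag(ee) <- 0
  ee[ee < 0] <- 0
  w$ee <- ee
  w
}

#' Simulate the network
#'
#' Runs the full developmental simulation. Per timestep, in order: synchronous
#' threshold dynamics, running-mean update, then (if plasticity is on) the
#' covariance update with clamping at 0, the two-step normalisation of the EE
#' block and, in the spatial variant, the Gaussian distance cap.
#'
#' The default engine is a compiled loop; `engine = "r"` runs the same
#' sequence through [step_dynamics()], [update_running_means()],
#' [covariance_update()] and [normalize_block()] (used for cross-checking,
#' and whenever a stimulus schedule is supplied).
#'
#' @param params A [sim_params()] object; `params$t_steps` steps are run.
#' @param w Optional [weight_matrix()] to start from; freshly initialised via
#'   [init_weights()] when `NULL`.
#' @param snapshot_every Record a copy of the EE block every this many steps
#'   (`NULL` to disable).
#' @param stimulus Optional forced-activation schedule: a named list mapping
#'   timestep to a vector of 1-based excitatory indices. Name `"0"` sets the
#'   initial state; at steps `t >= 1` the listed neurons are forced active
#'   after the threshold update. Implies `engine = "r"`.
#' @param record_raster Keep the full binary raster? Disable for long
#'   structure-only runs to save memory.
#' @param engine `"cpp"` (default) or `"r"`.
#' @param seed Integer seed; falls back to `params$seed`, or leaves the RNG
#'   stream untouched when both are `NULL`.
#' @return A `sim_result` list: `raster` (an [activity_raster()] of the E then
#'   I populations, `n_n` x `t_steps`, when recorded), `weights_final`,
#'   `weight_snapshots` (list of EE matrices), `snapshot_times`, `state`
#'   (final `network_state`) and `params`.
#' @examples
#' res <- simulate_network(sim_params(t_steps = 500, seed = 1))
#' dim(res$raster$values)
#' @export
simulate_network <- function(params, w = NULL, snapshot_every = NULL,
                             stimulus = NULL, record_raster = TRUE,
                             engine = c("cpp", "r"), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  engine <- match.arg(engine)
  if (!is.null(stimulus)) engine <- "r"
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(stimulus)) {
    if (is.null(names(stimulus)) || anyNA(suppressWarnings(
          as.integer(names(stimulus)))))
      stop("stimulus must be a named list keyed by timestep")
    idx <- unlist(stimulus)
    if (length(idx) && (any(idx < 1) || any(idx > params$n_e)))
      stop("stimulus indices must be valid excitatory neuron indices")
  }

  if (is.null(w)) w <- init_weights(params)
  p <- sample_baseline_rates(params)
  snap <- if (is.null(snapshot_every)) 0L else as.integer(snapshot_every)
  wmax <- if (params$spatial)
    distance_cap_matrix(spatial_layout(params$grid_side), params$a,
                        params$kappa)
  else matrix(0, 0, 0)

  if (engine == "cpp") {
    out <- .simulate_core(w$ee, w$ei, w$ie, w$ii, p$p_e, p$p_i, params$theta,
                          params$eta, params$t_steps, params$plasticity,
                          params$spatial, wmax, snap, record_raster,
                          numeric(params$n_e), numeric(params$n_i))
    state <- structure(list(x_e = drop(out$x_e), x_i = drop(out$x_i),
                            mean_e = drop(out$mean_e),
                            mean_i = drop(out$mean_i),
                            p_e = p$p_e, p_i = p$p_i, t = params$t_steps),
                       class = "network_state")
    raster <- if (record_raster)
      rbind(out$raster_e, out$raster_i) else NULL
    w$ee <- out$ee
    snapshots <- out$snapshots
    snap_times <- out$snapshot_times
  } else {
    state <- network_state(params, p)
    if (!is.null(stimulus[["0"]])) state$x_e[stimulus[["0"]]] <- 1
    raster <- if (record_raster)
      matrix(0L, params$n_n, params$t_steps) else NULL
    snapshots <- list(); snap_times <- integer()
    for (t in seq_len(params$t_steps)) {
      state <- step_dynamics(state, w, params)
      st <- stimulus[[as.character(t)]]
      if (!is.null(st)) state$x_e[st] <- 1
      state <- update_running_means(state)
      if (params$plasticity) {
        w <- covariance_update(w, state, params$eta)
        w$ee <- normalize_block(w$ee)
        if (params$spatial) w$ee <- pmin(w$ee, wmax)
      }
      if (record_raster) raster[, t] <- as.integer(c(state$x_e, state$x_i))
      if (snap > 0L && t %% snap == 0L) {
        snapshots[[length(snapshots) + 1L]] <- w$ee
        snap_times <- c(snap_times, t)
      }
    }
  }

  raster_obj <- if (record_raster)
    activity_raster(raster, dt = 1,
                    neuron_ids = c(paste0("E", seq_len(params$n_e)),
                                   paste0("I", seq_len(params$n_i))))
  else NULL
  structure(list(raster = raster_obj, weights_final = w,
                 weight_snapshots = snapshots,
                 snapshot_times = as.integer(unlist(snap_times)),
                 state = state, params = params),
            class = "sim_result")
}

#' @exportS3Method print sim_result
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$params$n_n, "neurons,", x$params$t_steps, "steps;",
      length(x$weight_snapshots), "EE snapshots;",
      if (is.null(x$raster)) "raster not recorded" else "raster recorded",
      "\n")
  invisible(x)
}
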