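#' Simulation parameters for the Hebbian assembly-formation network
#'
#' Constructs and validates the full parameter set of the binary
#' excitatory/inhibitory network. Defaults are the standard values for the
#' basic (non-spatial) model: 100 excitatory and 25 inhibitory neurons (the
#' fixed 4:1 E:I ratio), learning rate `eta = 0.03`, baseline activation
#' probabilities drawn from Normal(`mu = 4e-3`, `sigma = 3e-4`), and
#' activation threshold `theta = 0.1`. The spatial variant arranges the
#' excitatory population on a square toroidal grid and caps connection
#' strengths with a Gaussian of amplitude `a` and width `kappa`; its standard
#' configuration is 1024 E / 256 I neurons, `eta = 0.04`, `mu = 2e-3`,
#' `a = 0.1`, `kappa = 3`.
#'
#' @param n_e Number of excitatory neurons.
#' @param n_i Number of inhibitory neurons. Must equal `n_e / 4`.
#' @param eta Learning rate of the covariance plasticity rule.
#' @param mu Mean of the per-neuron baseline activation probability.
#' @param sigma Standard deviation of the baseline activation probability.
#' @param theta Activation threshold (proportion of maximal synaptic input a
#'   neuron needs in order to fire). Must lie in `[0, 1)`.
#' @param t_steps Number of timesteps to simulate (one step is one second of
#'   model time).
#' @param plasticity Logical; apply the covariance rule and renormalise the
#'   EE block every timestep?
#' @param spatial Logical; use the distance-dependent variant? Requires
#'   `n_e` to be a perfect square.
#' @param a Amplitude of the Gaussian connectivity cap (spatial variant).
#' @param kappa Width of the Gaussian connectivity cap, in grid units.
#' @param seed Optional integer seed recorded with the parameters and used by
#'   [simulate_network()].
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params()              # basic model defaults
#' p$n_e; p$eta
#' ps <- sim_params(n_e = 64, n_i = 16, spatial = TRUE)
#' @export
sim_params <- function(n_e = 100L, n_i = 25L, eta = 0.03, mu = 4e-3,
                       sigma = 3e-4, theta = 0.1, t_steps = 100000L,
                       plasticity = TRUE, spatial = FALSE, a = 0.1,
                       kappa = 3, seed = NULL) {
  n_e <- as.integer(n_e); n_i <- as.integer(n_i)
  stopifnot(n_e >= 1L, n_i >= 1L, t_steps >= 0L)
  if (n_e != 4L * n_i)
    stop("the network uses a fixed 4:1 E:I ratio: n_e must equal 4 * n_i")
  if (any(c(eta, mu, sigma, theta, a) < 0))
    stop("eta, mu, sigma, theta and a must all be non-negative")
  if (theta >= 1) stop("theta must be < 1")
  grid_side <- NA_integer_
  if (spatial) {
    grid_side <- as.integer(round(sqrt(n_e)))
    if (grid_side^2 != n_e)
      stop("spatial variant requires n_e to be a perfect square")
  }
  structure(list(n_e = n_e, n_i = n_i, n_n = n_e + n_i, eta = eta, mu = mu,
                 sigma = sigma, theta = theta, t_steps = as.integer(t_steps),
                 plasticity = isTRUE(plasticity), spatial = isTRUE(spatial),
                 a = a, kappa = kappa, grid_side = grid_side,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

#' @exportS3Method print sim_params
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$n_e, "E /", x$n_i, "I neurons;",
      "eta =", x$eta, "mu =", x$mu, "sigma =", x$sigma, "theta =", x$theta,
      "\n  t_steps =", x$t_steps,
      if (x$plasticity) "(plastic)" else "(frozen)",
      if (x$spatial) sprintf("spatial grid %dx%d, a = %g, kappa = %g",
                             x$grid_side, x$grid_side, x$a, x$kappa) else "",
      "\n")
  invisible(x)
}

#' Sample per-neuron baseline activation probabilities
#'
#' Each neuron's probability of spontaneous (noise-driven) activation is
#' drawn independently from Normal(`mu`, `sigma^2`) and clamped to `[0, 1]`
#' (a no-op at default values, where `mu` is three orders of magnitude above
#' zero relative to `sigma`, but it protects parameter sweeps).
#'
#' @param params A [sim_params()] object.
#' @return A list with probability vectors `p_e` (length `n_e`) and `p_i`
#'   (length `n_i`).
#' @examples
#' set.seed(1)
#' p <- sample_baseline_rates(sim_params())
#' mean(p$p_e)  # close to mu = 0.004
#' @export
sample_baseline_rates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  clamp01 <- function(v) pmin(1, pmax(0, v))
  list(p_e = clamp01(stats::rnorm(params$n_e, params$mu, params$sigma)),
       p_i = clamp01(stats::rnorm(params$n_i, params$mu, params$sigma)))
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key/value YAML mirroring the model parameter names: `n_e`, `n_i`,
#' `eta`, `mu`, `sigma`, `theta`, `a`, `kappa`, `T` (or `t_steps`), `seed`,
#' `spatial`, `plasticity`. Missing keys fall back to the [sim_params()]
#' defaults.
#'
#' @param path Path to the YAML file.
#' @return A `sim_params` object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$T) && is.null(cfg$t_steps)) cfg$t_steps <- cfg$T
  cfg$T <- NULL
  allowed <- names(formals(sim_params))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_params, cfg)
}
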