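#' Activity raster container
#'
#' Neurons x timesteps matrix of activity: binary for model output, real for
#' dF/F-like calcium traces. One timestep corresponds to `dt` seconds (1 by
#' default, matching the model's one-second timestep).
#'
#' @param values Numeric matrix, neurons in rows, timesteps in columns.
#' @param dt Seconds per timestep.
#' @param neuron_ids Optional character ids, one per row.
#' @return An `activity_raster` object.
#' @export
activity_raster <- function(values, dt = 1, neuron_ids = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) >= 1, dt > 0)
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  stopifnot(length(neuron_ids) == nrow(values))
  structure(list(values = values, dt = dt, neuron_ids = neuron_ids,
                 binary = all(values %in% c(0, 1))),
            class = "activity_raster")
}

#' @exportS3Method print activity_raster
print.activity_raster <- function(x, ...) {
  cat("<activity_raster>", nrow(x$values), "neurons x", ncol(x$values),
      "timesteps (dt =", x$dt, "s,",
      if (x$binary) "binary)" else "real-valued)", "\n")
  invisible(x)
}

as_raster_values <- function(raster) {
  if (inherits(raster, "activity_raster")) raster$values else as.matrix(raster)
}

#' Binarise a dF/F raster
#'
#' A neuron is marked active at a timestep when its trace exceeds its own mean
#' by two standard deviations. Zero-variance traces are mapped to all-zero
#' rows with a warning.
#'
#' @param dff A real-valued [activity_raster()] or matrix.
#' @return A binary [activity_raster()].
#' @export
binarize_dff <- function(dff) {
  v <- as_raster_values(dff)
  mu <- rowMeans(v)
  sd_ <- apply(v, 1, stats::sd)
  flat <- sd_ == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance trace(s) binarised to all-zero")
    sd_[flat] <- Inf
  }
  b <- (v > mu + 2 * sd_) * 1L
  activity_raster(b, dt = if (inherits(dff, "activity_raster")) dff$dt else 1,
                  neuron_ids = if (inherits(dff, "activity_raster"))
                    dff$neuron_ids else NULL)
}

#' Per-timestep count of active assembly members
#'
#' @param raster A binary [activity_raster()] or matrix.
#' @param assembly Integer vector of 1-based member indices.
#' @return Integer vector of length T: active members at each timestep.
#' @export
assembly_activity_trace <- function(raster, assembly) {
  v <- as_raster_values(raster)
  assembly <- as.integer(assembly)
  if (length(assembly) == 0) stop("assembly is empty")
  stopifnot(all(assembly >= 1), all(assembly <= nrow(v)))
  colSums(v[assembly, , drop = FALSE])
}

#' Detect assembly activation events in an activity trace
#'
#' Events are local maxima of the active-member count at which at least
#' `min_fraction` of the assembly is active, selected greedily in order of
#' descending peak height subject to a pairwise separation of at least
#' `min_separation` frames (when two candidate peaks are closer, the taller
#' one wins; plateaus contribute their first index).
#'
#' @param trace Per-timestep active-member counts
#'   (see [assembly_activity_trace()]).
#' @param assembly_size Number of neurons in the assembly.
#' @param min_separation Minimum frames between events.
#' @param min_fraction Minimum active fraction at an event.
#' @return An `event_series` list with sorted `event_times`, the `trace`, and
#'   the threshold used.
#' @examples
#' detect_assembly_events(c(0, 2, 6, 3, 0, 0, 0, 1, 7, 2), 10)$event_times
#' @export
detect_assembly_events <- function(trace, assembly_size, min_separation = 5,
                                   min_fraction = 0.5) {
  stopifnot(assembly_size >= 1)
  n <- length(trace)
  thr <- min_fraction * assembly_size
  # local maxima: strictly above previous value, at least equal to next
  # (plateaus keep their first index); boundary points compare one-sided
  prev <- c(-Inf, trace[-n])
  nxt <- c(trace[-1], -Inf)
  cand <- which(trace >= thr & trace > prev & trace >= nxt)
  keep <- integer()
  for (i in cand[order(-trace[cand], cand)]) {
    if (all(abs(keep - i) >= min_separation)) keep <- c(keep, i)
  }
  structure(list(event_times = sort(keep), trace = trace,
                 threshold = thr, assembly_size = assembly_size),
            class = "event_series")
}

#' @exportS3Method print event_series
print.event_series <- function(x, ...) {
  cat("<event_series>", length(x$event_times), "events over",
      length(x$trace), "timesteps (threshold", x$threshold, "active)\n")
  invisible(x)
}

#' Assembly event frequency of a raster
#'
#' Total number of detected activation events across all assemblies divided by
#' the raster length, in events per timestep.
#'
#' @param raster A binary [activity_raster()] or matrix.
#' @param assemblies An [assembly_set()].
#' @param ... Passed to [detect_assembly_events()].
#' @return Events per timestep.
#' @export
event_frequency <- function(raster, assemblies, ...) {
  stopifnot(inherits(assemblies, "assembly_set"),
            length(assemblies$assemblies) >= 1)
  v <- as_raster_values(raster)
  total <- sum(vapply(assemblies$assemblies, function(a) {
    length(detect_assembly_events(assembly_activity_trace(v, a),
                                  length(a), ...)$event_times)
  }, numeric(1)))
  total / ncol(v)
}

#' Activity build-up and persistence profile around assembly events
#'
#' For each event, counts active neurons inside the event's assembly, outside
#' it, and in total at lags `-window .. 0` relative to the event time, and the
#' number of assembly members active at both `t - 1` and `t` (persistence).
#' Averages over events; events closer than `window` steps to the raster start
#' are skipped.
#'
#' @param raster A binary [activity_raster()] or matrix.
#' @param assembly Integer vector of assembly member indices.
#' @param events An `event_series` for that assembly (or a vector of event
#'   times).
#' @param window Number of lags before the event to include.
#' @return A data.frame with columns `lag`, `within`, `outside`, `total`,
#'   `persistence` (persistence is NA at the earliest lag).
#' @export
buildup_profile <- function(raster, assembly, events, window = 10) {
  stopifnot(window >= 1)
  v <- as_raster_values(raster)
  times <- if (inherits(events, "event_series")) events$event_times
           else as.integer(events)
  if (length(times) == 0) stop("no events supplied")
  usable <- times[times > window]
  if (length(usable) < length(times))
    message(length(times) - length(usable),
            " event(s) too close to raster start skipped")
  if (length(usable) == 0) stop("no events far enough from the raster start")
  lags <- -window:0
  inside <- v[assembly, , drop = FALSE]
  outside <- v[-assembly, , drop = FALSE]
  acc <- matrix(0, length(lags), 4)
  for (t0 in usable) {
    ts <- t0 + lags
    w_in <- colSums(inside[, ts, drop = FALSE])
    w_out <- colSums(outside[, ts, drop = FALSE])
    pers <- c(NA, colSums(inside[, ts[-1], drop = FALSE] == 1 &
                            inside[, ts[-length(ts)], drop = FALSE] == 1))
    acc <- acc + cbind(w_in, w_out, w_in + w_out,
                       ifelse(is.na(pers), 0, pers))
  }
  acc <- acc / length(usable)
  data.frame(lag = lags, within = acc[, 1], outside = acc[, 2],
             total = acc[, 3],
             persistence = c(NA, acc[-1, 4]))
}

#' Generate a synthetic dF/F raster with planted synchronous assemblies
#'
#' Emulates calcium-imaging data at 1 s resolution: the population is split
#' into `k` disjoint assemblies; each assembly fires synchronous events at
#' Poisson times (thinned to a minimum separation of 5 frames); each member's
#' trace is the unit-amplitude event train convolved with an exponential-decay
#' kernel `exp(-lag / decay_tau)` plus i.i.d. Gaussian noise.
#'
#' @param n Number of neurons.
#' @param t_steps Number of frames.
#' @param k Number of planted assemblies.
#' @param event_rate Per-assembly event probability per frame.
#' @param decay_tau Decay time constant of the kernel, in frames (0 for a
#'   spike-only kernel).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional integer seed.
#' @return A list with `dff` (a real-valued [activity_raster()]), `truth` (an
#'   [assembly_set()]) and `event_times` (list of per-assembly event frames).
#' @export
generate_dff_fixture <- function(n = 100, t_steps = 5000, k = 5,
                                 event_rate = 0.01, decay_tau = 2,
                                 noise_sd = 0.1, seed = NULL) {
  stopifnot(n >= k, t_steps >= 1, k >= 1, event_rate > 0, decay_tau >= 0,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  memb <- rep(seq_len(k), sizes)
  truth <- membership_to_assembly_set(memb, source = "truth")
  kern_len <- if (decay_tau > 0) max(1L, ceiling(6 * decay_tau)) else 1L
  kern <- exp(-(seq_len(kern_len) - 1) / max(decay_tau, 1e-12))
  if (decay_tau == 0) kern <- 1
  v <- matrix(stats::rnorm(n * t_steps, 0, noise_sd), n, t_steps)
  event_times <- vector("list", k)
  for (a in seq_len(k)) {
    cand <- which(stats::runif(t_steps) < event_rate)
    times <- integer()
    for (tt in cand) if (!length(times) || tt - times[length(times)] >= 5)
      times <- c(times, tt)
    event_times[[a]] <- times
    if (length(times)) {
      # causal convolution of the event train with the decay kernel
      sig <- numeric(t_steps)
      for (tt in times) {
        span <- tt:min(t_steps, tt + kern_len - 1L)
        sig[span] <- sig[span] + kern[seq_along(span)]
      }
      v[truth$assemblies[[a]], ] <-
        v[truth$assemblies[[a]], , drop = FALSE] +
        matrix(sig, length(truth$assemblies[[a]]), t_steps, byrow = TRUE)
    }
  }
  list(dff = activity_raster(v), truth = truth, event_times = event_times)
}
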