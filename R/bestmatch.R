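#' Best-match similarity between two collections of assemblies
#'
#' Pairwise assembly similarity is the Jaccard index
#' `s^(A, B) = |A n B| / |A u B|`; the score between the collections is the
#' mean, over every assembly on either side, of its best Jaccard match on the
#' other side:
#' `s = (sum_A max_B s^ + sum_B max_A s^) / (|A| + |B|)`.
#' The score is symmetric, lies in `[0, 1]`, equals 1 iff the collections are
#' identical as sets of sets, and 0 when every pair is disjoint. Overlapping
#' collections (e.g. ICA output) are allowed. An empty side yields 0.
#'
#' @param a,b [assembly_set()] objects (or plain lists of index vectors).
#' @return The best-match score in `[0, 1]`.
#' @examples
#' A <- assembly_set(list(1:2, 3:4), 4, source = "truth")
#' B <- assembly_set(list(1:3, 4), 4, source = "truth")
#' best_match_score(A, B)  # 7/12
#' @export
best_match_score <- function(a, b) {
  la <- if (inherits(a, "assembly_set")) a$assemblies else a
  lb <- if (inherits(b, "assembly_set")) b$assemblies else b
  if (length(la) == 0 || length(lb) == 0) return(0)
  jac <- matrix(0, length(la), length(lb))
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    inter <- length(intersect(la[[i]], lb[[j]]))
    jac[i, j] <- inter / (length(la[[i]]) + length(lb[[j]]) - inter)
  }
  (sum(apply(jac, 1, max)) + sum(apply(jac, 2, max))) /
    (length(la) + length(lb))
}

#' Autosimilarity decay curve of sampled assembly sets
#'
#' Given assembly sets sampled at uniform intervals, the autosimilarity at lag
#' `dt` is the mean best-match score over all sample pairs separated by `dt`.
#' At `dt = 0` the score is exactly 1. Its decay over `dt` measures assembly
#' turnover.
#'
#' @param samples List of [assembly_set()] objects sampled at uniform
#'   intervals, in time order.
#' @param interval Timesteps between consecutive samples.
#' @param times Optional explicit sample times (must be uniformly spaced by
#'   `interval`).
#' @return A data.frame with columns `dt`, `similarity`, `n_pairs`.
#' @export
autosimilarity_curve <- function(samples, interval, times = NULL) {
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  if (!is.null(times)) {
    d <- diff(sort(times))
    if (length(unique(d)) != 1 || d[1] != interval)
      stop("sample times must be uniformly spaced by `interval`")
  }
  sims <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n)
    sims[i, j] <- if (i == j) 1 else best_match_score(samples[[i]],
                                                      samples[[j]])
  out <- lapply(0:(n - 1), function(lag) {
    vals <- sims[cbind(seq_len(n - lag), seq_len(n - lag) + lag)]
    data.frame(dt = lag * interval, similarity = mean(vals),
               n_pairs = length(vals))
  })
  do.call(rbind, out)
}

#' Fit an exponential decay to an autosimilarity curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `y = beta_baseline + beta_amplitude * exp(-dt / beta_decay)` to the
#' `dt > 0` points of the curve. Initial values: baseline `min(y)`, amplitude
#' `max(y) - min(y)`, decay one third of the `dt` range; on failure, restarts
#' from jittered starting points. A constant curve is flagged degenerate
#' (amplitude ~ 0, no meaningful decay constant).
#'
#' @param curve A data.frame with columns `dt` and `similarity` (as returned
#'   by [autosimilarity_curve()]), or numeric vectors via `dt`/`y`.
#' @param dt,y Alternative explicit vectors.
#' @param restarts Number of jittered restarts after an initial failure.
#' @return An `exponential_fit` list: `beta_baseline`, `beta_amplitude`,
#'   `beta_decay` (timesteps), `r_squared`, `degenerate`, and the `fitted`
#'   values.
#' @export
fit_exponential <- function(curve = NULL, dt = NULL, y = NULL, restarts = 20) {
  if (!is.null(curve)) {
    dt <- curve$dt
    y <- curve$similarity
  }
  keep <- dt > 0
  dt <- dt[keep]; y <- y[keep]
  if (length(dt) < 4) stop("need at least 4 points with dt > 0")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-24 || diff(range(y)) < 1e-12) {
    return(structure(list(beta_baseline = mean(y), beta_amplitude = 0,
                          beta_decay = NA_real_, r_squared = NA_real_,
                          degenerate = TRUE, fitted = rep(mean(y), length(y)),
                          dt = dt, y = y),
                     class = "exponential_fit"))
  }
  dat <- data.frame(dt = dt, y = y)
  start <- list(b0 = min(y), b1 = max(y) - min(y), tau = diff(range(dt)) / 3)
  fit <- NULL
  for (r in 0:restarts) {
    st <- if (r == 0) start else
      lapply(start, function(v) v * stats::runif(1, 0.3, 3) + 1e-8)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b0 + b1 * exp(-dt / tau), data = dat, start = st,
                        lower = c(-Inf, -Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("exponential fit did not converge after ", restarts, " restarts; ",
         "y range [", min(y), ", ", max(y), "]")
  co <- stats::coef(fit)
  fitted_y <- stats::fitted(fit)
  r2 <- 1 - sum((y - fitted_y)^2) / ss_tot
  structure(list(beta_baseline = unname(co["b0"]),
                 beta_amplitude = unname(co["b1"]),
                 beta_decay = unname(co["tau"]),
                 r_squared = r2,
                 degenerate = abs(co["b1"]) < 1e-10,
                 fitted = as.numeric(fitted_y), dt = dt, y = y),
            class = "exponential_fit")
}

#' @exportS3Method print exponential_fit
print.exponential_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<exponential_fit> degenerate (constant curve), baseline",
        signif(x$beta_baseline, 4), "\n")
  } else {
    cat("<exponential_fit> y =", signif(x$beta_baseline, 4), "+",
        signif(x$beta_amplitude, 4), "* exp(-dt /",
        paste0(signif(x$beta_decay, 4), ");"),
        "R^2 =", signif(x$r_squared, 4), "\n")
  }
  invisible(x)
}
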