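test_that("dF/F binarisation thresholds at mean plus two SDs", {
  # trace with mean ~0 and SD ~1 (threshold ~2.01): 2.1 crosses, 1.9 does not
  base <- c(rep(c(-1, 1), 500), 1.9, 2.1)
  b <- binarize_dff(rbind(base))
  expect_equal(unname(b$values[1, 1001]), 0)
  expect_equal(unname(b$values[1, 1002]), 1)
  expect_equal(sum(b$values), 1)

  # constant trace: all zeros, with a warning
  expect_warning(bc <- binarize_dff(rbind(rep(1, 50))), "zero-variance")
  expect_true(all(bc$values == 0))

  # sparse binary traces keep their positives (mean + 2 SD < 1 at low rates)
  set.seed(2)
  sparse <- rbind(stats::rbinom(2000, 1, 0.05))
  bs <- binarize_dff(sparse)
  expect_equal(bs$values, sparse * 1L, ignore_attr = TRUE)
})

test_that("assembly activity traces count active members", {
  r <- rbind(c(1, 0, 1, 0), c(0, 0, 1, 1), c(1, 1, 1, 0))
  expect_equal(assembly_activity_trace(r, c(1, 3)), c(2, 1, 2, 0))
  expect_equal(assembly_activity_trace(r, 1:3), c(2, 1, 3, 1))
  expect_equal(assembly_activity_trace(matrix(0, 3, 4), 1:3), rep(0, 4))
  expect_error(assembly_activity_trace(r, integer()), "empty")
})

test_that("event detection applies the occupancy and separation rules", {
  # no activity, no events
  expect_length(detect_assembly_events(rep(0, 20), 10)$event_times, 0)

  # two well-separated peaks above half occupancy
  ev <- detect_assembly_events(c(0, 2, 6, 3, 0, 0, 0, 1, 7, 2), 10)
  expect_equal(ev$event_times, c(3, 9))

  # conflicting peaks closer than 5 frames: the taller one wins
  ev2 <- detect_assembly_events(c(0, 0, 6, 0, 0, 7, 0, 0, 0, 0), 10)
  expect_equal(ev2$event_times, 6)

  # property: rules hold on random traces
  set.seed(4)
  for (r in 1:20) {
    tr <- stats::rpois(200, 2) + stats::rbinom(200, 1, 0.05) * 8
    ev <- detect_assembly_events(tr, 10)$event_times
    expect_true(all(tr[ev] >= 5))
    if (length(ev) > 1) expect_true(all(diff(ev) >= 5))
  }
})

test_that("best-match score satisfies its defining identities", {
  A <- assembly_set(list(1:2, 3:4), 4, source = "truth")
  expect_equal(best_match_score(A, A), 1)
  B <- assembly_set(list(1:3, 4), 4, source = "truth")
  expect_equal(best_match_score(A, B), 7 / 12)
  expect_equal(best_match_score(B, A), 7 / 12)  # symmetry
  D <- assembly_set(list(5:6, 7:8), 8, source = "ica")
  A8 <- assembly_set(list(1:2, 3:4), 8, source = "ica")
  expect_equal(best_match_score(A8, D), 0)  # pairwise disjoint
  expect_equal(best_match_score(A, assembly_set(list(), 4, "ica")), 0)
  set.seed(5)
  for (r in 1:10) {
    X <- membership_to_assembly_set(sample(1:3, 20, replace = TRUE), "truth")
    Y <- membership_to_assembly_set(sample(1:4, 20, replace = TRUE), "truth")
    s <- best_match_score(X, Y)
    expect_true(s >= 0 && s <= 1)
    expect_equal(s, best_match_score(Y, X))
  }
})

test_that("autosimilarity is one at zero lag and flat for random turnover", {
  set.seed(6)
  samples <- lapply(1:12, function(i)
    membership_to_assembly_set(sample(rep(1:5, 20)), source = "truth"))
  curve <- autosimilarity_curve(samples, interval = 1000)
  expect_equal(curve$similarity[curve$dt == 0], 1)
  pos <- curve$similarity[curve$dt > 0 & curve$n_pairs >= 3]
  expect_lt(max(pos) - min(pos), 0.1)   # flat at the random-overlap baseline
  expect_lt(mean(pos), 0.5)
  expect_error(autosimilarity_curve(samples, 1000,
                                    times = c(0, 1000, 3000, 4000)),
               "uniformly spaced")
})

test_that("exponential fits recover known decay parameters", {
  dt <- seq(500, 20000, by = 500)
  y <- 0.2 + 0.7 * exp(-dt / 5000)
  fit <- fit_exponential(dt = dt, y = y)
  expect_equal(fit$beta_baseline, 0.2, tolerance = 1e-6)
  expect_equal(fit$beta_amplitude, 0.7, tolerance = 1e-6)
  expect_equal(fit$beta_decay, 5000, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)

  # noisy recovery of the decay constant
  set.seed(7)
  errs <- replicate(20, {
    yn <- y + stats::rnorm(length(y), 0, 0.01)
    abs(fit_exponential(dt = dt, y = yn)$beta_decay - 5000) / 5000
  })
  expect_lt(mean(errs), 0.1)

  # constant curve: degenerate flag
  flat <- fit_exponential(dt = dt, y = rep(0.4, length(dt)))
  expect_true(flat$degenerate)
  expect_equal(flat$beta_amplitude, 0)
  expect_error(fit_exponential(dt = 1:3, y = 1:3), "at least 4")
})

test_that("build-up profiles match hand-built activation sequences", {
  # assembly of 6 neurons switching on only at the event time
  r <- matrix(0, 10, 30)
  r[1:6, 20] <- 1
  prof <- buildup_profile(r, 1:6, events = 20, window = 5)
  expect_equal(prof$within, c(0, 0, 0, 0, 0, 6))
  expect_equal(prof$outside, rep(0, 6))

  # disjoint pairs at t-3, t-2, t-1 then the full assembly at t:
  # persistence stays 0 until the final transition
  r2 <- matrix(0, 10, 30)
  r2[1:2, 17] <- 1; r2[3:4, 18] <- 1; r2[5:6, 19] <- 1; r2[1:6, 20] <- 1
  prof2 <- buildup_profile(r2, 1:6, events = 20, window = 4)
  expect_equal(prof2$within, c(0, 2, 2, 2, 6))
  expect_equal(prof2$persistence[-1], c(0, 0, 0, 2))
  expect_equal(prof2$outside, rep(0, 5))

  # events too close to the raster start are skipped
  expect_error(suppressMessages(buildup_profile(r2, 1:6, events = 3,
                                                window = 5)),
               "far enough")
})

test_that("the planted dF/F fixture is recovered by the analysis chain", {
  # degenerate kernel and zero noise: binarisation recovers the event raster
  fx0 <- generate_dff_fixture(n = 20, t_steps = 400, k = 2, event_rate = 0.02,
                              decay_tau = 0, noise_sd = 0, seed = 8)
  b0 <- binarize_dff(fx0$dff)
  for (a in 1:2) {
    tr <- assembly_activity_trace(b0, fx0$truth$assemblies[[a]])
    expect_equal(which(tr == length(fx0$truth$assemblies[[a]])),
                 fx0$event_times[[a]])
  }

  # default fixture: planted events recovered within one frame
  fx <- generate_dff_fixture(seed = 9)
  b <- binarize_dff(fx$dff)
  hits <- tot <- 0
  for (a in seq_along(fx$truth$assemblies)) {
    tr <- assembly_activity_trace(b, fx$truth$assemblies[[a]])
    ev <- detect_assembly_events(tr, length(fx$truth$assemblies[[a]]))
    for (t in fx$event_times[[a]]) {
      tot <- tot + 1
      hits <- hits + any(abs(ev$event_times - t) <= 1)
    }
  }
  expect_gte(hits / tot, 0.95)

  # ICA recovers the planted assemblies from the binarised raster
  ic <- ica_detect_assemblies(b, seed = 10)
  expect_gte(best_match_score(ic, fx$truth), 0.9)
})

test_that("the Marchenko-Pastur bound rejects unstructured rasters", {
  khats <- vapply(1:10, function(s) {
    set.seed(s)
    r <- matrix(stats::rbinom(100 * 10000, 1, 0.05), 100)
    attr(ica_detect_assemblies(r), "k_hat")
  }, integer(1))
  expect_gte(sum(khats == 0), 9)
})

test_that("event frequency counts planted events and scales with structure", {
  # exactly 10 well-separated synchronous events
  r <- matrix(0, 10, 500)
  times <- seq(20, 470, by = 50)
  r[1:10, times] <- 1
  aset <- assembly_set(list(1:10), 10, source = "truth")
  expect_equal(event_frequency(r, aset), 10 / 500)
  expect_equal(event_frequency(matrix(0, 10, 100), aset), 0)
})
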