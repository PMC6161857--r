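# Minimal 4E/1I network with hand-set weights for direct formula checks.
tiny_net <- function(ee_col = 0, ei_val = 0) {
  ee <- matrix(0, 4, 4)
  ee[, 1] <- ee_col  # neuron 1 drives everyone else with this weight
  diag(ee) <- 0
  ei <- matrix(ei_val, 4, 1)
  weight_matrix(ee, ei, matrix(0, 1, 4), matrix(0, 1, 1))
}

test_that("threshold rule follows the strict-inequality activation formula", {
  p <- sim_params(n_e = 4, n_i = 1, theta = 0.1, mu = 0, sigma = 0,
                  t_steps = 1)

  # excitatory drive 0.2, no inhibition: 0.2 - 0.1 > 0 -> active
  st <- network_state(p, p = list(p_e = rep(0, 4), p_i = 0),
                      x_e = c(1, 0, 0, 0))
  st1 <- step_dynamics(st, tiny_net(ee_col = 0.2), p)
  expect_equal(st1$x_e[2:4], rep(1, 3))
  expect_equal(st1$x_e[1], 0)  # no self-drive (autapse-free)

  # add inhibitory drive 0.15: 0.2 - 0.15 - 0.1 < 0 -> inactive
  st$x_i <- 1
  st2 <- step_dynamics(st, tiny_net(ee_col = 0.2, ei_val = 0.15), p)
  expect_equal(st2$x_e, rep(0, 4))

  # noise term alone suffices: beta = 1 + theta, Theta(1 + theta - theta) = 1
  stn <- network_state(p, p = list(p_e = rep(1, 4), p_i = 1))
  st3 <- step_dynamics(stn, tiny_net(), p)
  expect_equal(st3$x_e, rep(1, 4))
  expect_equal(st3$x_i, 1)

  # exact threshold input does not activate (Theta(0) = 0)
  st4 <- step_dynamics(network_state(p, p = list(p_e = rep(0, 4), p_i = 0),
                                     x_e = c(1, 0, 0, 0)),
                       tiny_net(ee_col = 0.1), p)
  expect_equal(st4$x_e, rep(0, 4))
})

test_that("online running means equal the stored-history mean", {
  p <- sim_params(n_e = 20, n_i = 5, mu = 0.3, sigma = 0.05, t_steps = 1)
  set.seed(3)
  w <- init_weights(p)
  st <- network_state(p)
  hist_e <- matrix(NA, 20, 1000)
  for (t in 1:1000) {
    st <- update_running_means(step_dynamics(st, w, p))
    hist_e[, t] <- st$x_e
    if (t %in% c(1, 4)) {
      expect_equal(st$mean_e, rowMeans(hist_e[, 1:t, drop = FALSE]))
    }
  }
  expect_equal(st$mean_e, rowMeans(hist_e), tolerance = 1e-12)
  # first step: mean equals the state itself; (1,0,0,1) averages to 0.5
  expect_equal(mean(c(1, 0, 0, 1)), 0.5)
})

test_that("covariance update matches the learning rule and clamps at zero", {
  p <- sim_params(n_e = 4, n_i = 1, t_steps = 1)
  st <- network_state(p, p = list(p_e = rep(0, 4), p_i = 0))
  st$t <- 10L

  # x_i = x_j = 1, means 0.5, eta 0.03 -> dw = 0.03 * 0.25 = 0.0075
  st$x_e <- c(1, 1, 0, 0); st$mean_e <- c(0.5, 0.5, 0.5, 0.5)
  w0 <- tiny_net()
  w1 <- covariance_update(w0, st, eta = 0.03)
  expect_equal(w1$ee[1, 2], 0.0075)
  expect_equal(w1$ee[2, 1], 0.0075)
  expect_equal(diag(w1$ee), rep(0, 4))

  # all states at their means -> zero update
  st$x_e <- c(0.5, 0.5, 0.5, 0.5) * 0 + st$mean_e
  expect_equal(covariance_update(w0, st, 0.03)$ee, w0$ee)

  # raw dw = 0.03 * (1 - 0.2) * (0 - 0.5) = -0.012 clamps 0.001 to 0
  st$x_e <- c(1, 0, 0, 0); st$mean_e <- c(0.2, 0.5, 0, 0)
  wsmall <- tiny_net(); wsmall$ee[1, 2] <- 0.001
  w2 <- covariance_update(wsmall, st, 0.03)
  expect_equal(w2$ee[1, 2], 0)

  # untouched blocks
  expect_identical(w2$ei, wsmall$ei)
  expect_identical(w2$ie, wsmall$ie)
  expect_identical(w2$ii, wsmall$ii)
})

test_that("a network with zero baseline drive and zero state stays silent", {
  p <- sim_params(mu = 0, sigma = 0, t_steps = 200, seed = 5)
  res <- simulate_network(p)
  expect_true(all(res$raster$values == 0))
})

test_that("same seed gives identical results; engines agree step for step", {
  p <- sim_params(n_e = 40, n_i = 10, mu = 0.02, t_steps = 300, seed = 21)
  a <- simulate_network(p, engine = "cpp")
  b <- simulate_network(p, engine = "cpp")
  expect_identical(a$raster$values, b$raster$values)
  expect_identical(a$weights_final$ee, b$weights_final$ee)

  r <- simulate_network(p, engine = "r")
  expect_equal(r$raster$values, a$raster$values)
  expect_equal(r$weights_final$ee, a$weights_final$ee, tolerance = 1e-12)
  expect_equal(r$state$mean_e, a$state$mean_e, tolerance = 1e-12)

  expect_false(identical(
    simulate_network(sim_params(t_steps = 50, seed = 1))$raster$values,
    simulate_network(sim_params(t_steps = 50, seed = 2))$raster$values))
})

test_that("plasticity conserves row sums and bounds throughout a run", {
  p <- sim_params(n_e = 40, n_i = 10, mu = 0.02, t_steps = 400, seed = 8)
  res <- simulate_network(p, snapshot_every = 50, record_raster = FALSE)
  for (ee in res$weight_snapshots) {
    rs <- rowSums(ee)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
    expect_true(all(ee >= 0 & ee <= 1))
    expect_true(all(diag(ee) == 0))
  }
})

test_that("row-stochastic EE matrices have leading eigenvalue one", {
  set.seed(13)
  w <- init_weights(sim_params())
  ev <- eigen(w$ee, only.values = TRUE)$values
  lead <- max(Re(ev))
  expect_lt(lead, 1 + 1e-9)
  expect_equal(lead, 1, tolerance = 1e-6)  # dense positive matrix: irreducible
})

test_that("stimulus schedules force excitatory neurons active", {
  p <- sim_params(n_e = 20, n_i = 5, mu = 0, sigma = 0, t_steps = 10,
                  plasticity = FALSE, seed = 2)
  res <- simulate_network(p, stimulus = list("0" = 1:3, "4" = c(7, 8)))
  v <- res$raster$values
  expect_true(all(v[7:8, 4] == 1))
  expect_error(simulate_network(p, stimulus = list("1" = 99)),
               "valid excitatory")
  expect_error(simulate_network(p, stimulus = list(1:2)), "named list")
})
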