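test_that("fixed points satisfy the closed form to machine precision", {
  fp0 <- fixed_points(0)
  expect_equal(fp0$theta_stable, 0)
  expect_equal(fp0$theta_unstable, 0) # SNIC point
  fp <- fixed_points(-1.2)
  expect_equal(cos(fp$theta_unstable), -1 / 11, tolerance = 1e-14)
  expect_equal(fp$theta_unstable, 1.6618311, tolerance = 1e-6)
  expect_equal(fp$theta_stable, -fp$theta_unstable)
  # theta-dot vanishes at both fixed points
  for (i in c(-0.3, -1.2, -5)) {
    f <- fixed_points(i)
    for (th in c(f$theta_stable, f$theta_unstable)) {
      expect_lt(abs((1 - cos(th)) + (1 + cos(th)) * i), 1e-12)
    }
  }
  expect_false(fixed_points(0.5)$exists) # cos theta* = 3 > 1
  expect_error(fixed_points(1), "degenerate")
})

test_that("noiseless resting start stays at the fixed point with zero seizure fraction", {
  net <- random_test_network(6, directed = TRUE, seed = 2)
  p <- fast_params(k = 0, n_steps = 5000, noise_sd = 0)
  sim <- simulate_theta(net, p, return_trace = TRUE)
  expect_identical(sim$seizure_fraction, rep(0, 6))
  fp <- fixed_points(p$i_o)
  # parked at the fixed point up to the single-precision trig residual
  expect_lt(max(abs(sim$traces[[1]] - fp$theta_stable)), 1e-6)
})

test_that("supercritical drive gives perpetual rotation at the closed-form period", {
  net <- icto_network(matrix(0, 2, 2))
  p <- theta_params(i_o = 0.5, noise_sd = 0, k = 0, n_steps = 5000, seed = 1)
  expect_warning(sim <- simulate_theta(net, p, return_trace = TRUE),
                 "oscillates")
  expect_equal(sim$seizure_fraction, rep(1, 2))
  tr <- sim$traces[[1]][, 1]
  d <- diff(tr)
  d[d < -pi] <- d[d < -pi] + 2 * pi
  period <- (length(tr) * p$dt) / (sum(d) / (2 * pi))
  expect_equal(period, pi / sqrt(0.5), tolerance = 0.02) # Euler O(dt) bias
})

test_that("simulation is reproducible and permutation-equivariant", {
  net <- random_test_network(8, directed = TRUE, seed = 3)
  p <- fast_params(k = 60, n_steps = 1e4, n_realizations = 2)
  a <- simulate_theta(net, p)
  b <- simulate_theta(net, p)
  expect_identical(a$per_realization, b$per_realization)

  # relabeling nodes and permuting their noise streams gives statistically
  # identical dynamics; bitwise equality is unattainable because the
  # coupling sum is accumulated in a different order and the dynamics are
  # chaotic, so compare at estimation accuracy
  perm <- sample(8)
  noise <- lapply(1:2, function(r) ictonet:::make_noise_matrix(p, 8, r))
  base <- simulate_theta(net, p, noise = noise)
  net_p <- icto_network(net$weights[perm, perm], directed = TRUE)
  sim_p <- simulate_theta(net_p, p,
                          noise = lapply(noise, function(m) m[, perm]))
  expect_equal(sim_p$seizure_fraction, base$seizure_fraction[perm],
               tolerance = 0.02)
})

test_that("mean seizure fraction is nondecreasing in K under common noise", {
  net <- generate_network(topology = "random_regular_directed", n_nodes = 12,
                          mean_degree = 2, seed = 4)
  p <- fast_params(n_steps = 2e4)
  noise <- list(ictonet:::make_noise_matrix(p, 12, 1))
  fr <- vapply(c(0, 60, 180), function(k) {
    p$k <- k
    mean(simulate_theta(net, p, noise = noise)$seizure_fraction)
  }, numeric(1))
  expect_true(all(diff(fr) > -0.02))
})

test_that("halving dt changes a deterministic oscillating trajectory only at O(dt)", {
  net <- icto_network(matrix(0, 1, 1))
  run <- function(dt) {
    p <- theta_params(i_o = 0.5, noise_sd = 0, k = 0, dt = dt,
                      n_steps = round(10 / dt), seed = 1)
    suppressWarnings(simulate_theta(net, p, return_trace = TRUE))$traces[[1]]
  }
  tr1 <- run(0.01)
  tr2 <- run(0.005)
  d <- abs(tr1[nrow(tr1), 1] - tr2[nrow(tr2), 1])
  d <- min(d, 2 * pi - d) # phases live on the circle
  expect_lt(d, 0.15) # empirically ~ |T/period'' | * dt
})

test_that("saddle-crossing classifier flags exactly one epoch for a single spike", {
  fp <- fixed_points(-1.2)
  rest1 <- rep(fp$theta_stable, 50)
  up <- seq(fp$theta_stable, pi, length.out = 60)[-1] # crosses theta_u once
  wrap <- seq(-pi, fp$theta_stable, length.out = 40)[-1] # returns from below
  rest2 <- rep(fp$theta_stable, 50)
  trace <- c(rest1, up, wrap, rest2)
  flags <- classify_epileptiform(trace, -1.2)
  runs <- rle(flags)
  expect_equal(sum(runs$values), 1) # one contiguous epileptiform epoch
  expect_false(flags[1])
  expect_false(flags[length(flags)])
  expect_true(any(flags))

  expect_false(any(classify_epileptiform(rep(fp$theta_stable, 100), -1.2)))
  # a perpetually rotating phase is flagged exactly on the firing arc
  # (from theta_u up through the antipode back to theta_s)
  rot <- ((seq_len(5000) * 0.02 + fp$theta_stable + pi) %% (2 * pi)) - pi
  arc <- (2 * pi - (fp$theta_unstable - fp$theta_stable)) / (2 * pi)
  expect_equal(mean(classify_epileptiform(rot, -1.2)), arc, tolerance = 0.02)
})

test_that("amplitude-threshold classifier distinguishes rest from sustained rotation", {
  fp <- fixed_points(-1.2)
  cfg <- classifier_config(method = "amplitude_threshold",
                           amp_threshold = 0.9, smooth_window = 10)
  expect_false(any(classify_epileptiform(rep(fp$theta_stable, 200), -1.2, cfg)))
  # with a window spanning most of a rotation, sustained spiking stays
  # flagged through the brief transits past the resting phase
  # window of one full rotation (2*pi/0.05 = 126 samples) averages the
  # phase-distance observable to ~1 with negligible ripple
  cfg_wide <- classifier_config(method = "amplitude_threshold",
                                amp_threshold = 0.9, smooth_window = 126)
  rot <- ((seq_len(2000) * 0.05) %% (2 * pi)) - pi
  expect_gt(mean(classify_epileptiform(rot, -1.2, cfg_wide)), 0.9)
  expect_warning(classify_epileptiform(rep(0.1, 100), 0.5), "epileptiform")
})

test_that("simulation aborts on phase blow-up and rejects bad inputs", {
  net <- chain_network(3)
  p <- fast_params(n_steps = 100)
  bad_noise <- list(matrix(Inf, 100, 3))
  expect_error(simulate_theta(net, p, noise = bad_noise), "blow-up|non-finite")
  expect_error(theta_params(dt = -1), "dt")
  expect_error(theta_params(noise_sd = -1), "noise_sd")
})
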