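test_that("uncoupled oscillators drift linearly (closed form)", {
  omega <- 2 * pi * c(25, 30, 42.5, 50)
  K <- matrix(0, 4, 4)
  th0 <- c(0, 1, 2, 3)
  traj <- simulate_trial(omega, K, trial_config(), theta0 = th0)
  expected <- outer(traj$times, omega) + rep(th0, each = length(traj$times))
  expect_equal(traj$theta, expected, tolerance = 1e-12)
  ## rate proxy equals the feedforward frequency exactly
  rr <- rate_readouts(traj, omega / (2 * pi))
  expect_equal(rr$figure_rate, mean(omega) / (2 * pi), tolerance = 1e-9)
  expect_equal(rr$rate_difference, 0, tolerance = 1e-9)
})

test_that("the fixed-step integrator matches an adaptive-step oracle", {
  skip_if_not_installed("deSolve")
  set.seed(31)
  N <- 6
  K <- matrix(runif(N * N, 0, 20), N, N)
  K <- (K + t(K)) / 2
  diag(K) <- 0
  omega <- 2 * pi * runif(N, 25, 50)
  th0 <- runif(N, 0, 2 * pi)
  traj <- simulate_trial(omega, K, trial_config(substeps = 2), theta0 = th0)
  rhs <- function(t, th, p) {
    list(omega + colMeans(K * sin(outer(th, th, function(a, b) a - b))))
  }
  ode <- deSolve::ode(th0, traj$times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(traj$theta - ode[, -1])), 1e-4)
})

test_that("two coupled oscillators lock at the analytic Arnold boundary", {
  ## relative phase obeys dphi/dt = dw - K12 sin(phi): locking iff
  ## |dw| <= K12; sweep K12 at fixed detuning and check the boundary
  dw <- 2                      # rad/s
  cfg <- trial_config(duration = 3)
  k_grid <- seq(0.5, 3.5, by = 0.25)
  locked <- sapply(k_grid, function(k12) {
    K <- matrix(c(0, k12, k12, 0), 2, 2)
    omega <- 2 * pi * 40 + c(0, dw)
    traj <- simulate_trial(omega, K, cfg, theta0 = c(0, 0))
    phi <- traj$theta[, 2] - traj$theta[, 1]
    i0 <- which(traj$times >= 2.5)[1]
    abs(phi[length(phi)] - phi[i0]) / (3 - 2.5) < 0.1
  })
  boundary <- k_grid[which(locked)[1]]
  expect_lte(abs(boundary - dw), 0.25 + 1e-9)  # within one grid step of K = dw
  expect_true(all(locked[k_grid >= dw + 0.25]))
  expect_false(any(locked[k_grid <= dw - 0.5]))
})

test_that("order parameter hand cases are exact", {
  expect_equal(order_parameter(rep(1.3, 7))$r, 1, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi))$r, 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2))$r, sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(order_parameter(numeric(0)), "empty")
})

test_that("trial synchrony has the expected invariances and limits", {
  set.seed(32)
  ## strong identical-frequency coupling converges to full synchrony
  N <- 20
  K <- matrix(30, N, N)
  diag(K) <- 0
  omega <- rep(2 * pi * 40, N)
  cfg <- trial_config()
  traj <- simulate_trial(omega, K, cfg)
  r_series_start <- order_parameter(traj$theta[1, ])$r
  expect_gt(trial_synchrony(traj, cfg), r_series_start)
  expect_gt(trial_synchrony(traj, cfg), 0.99)
  ## invariance under a global phase shift and under 2 pi jumps
  traj2 <- traj
  traj2$theta <- traj$theta + 1.234
  expect_equal(trial_synchrony(traj2, cfg), trial_synchrony(traj, cfg),
               tolerance = 1e-12)
  traj3 <- traj
  traj3$theta[, 1] <- traj3$theta[, 1] + 2 * pi
  expect_equal(trial_synchrony(traj3, cfg), trial_synchrony(traj, cfg),
               tolerance = 1e-12)
  expect_equal(pairwise_plv(traj3, cfg), pairwise_plv(traj, cfg),
               tolerance = 1e-12)
  ## incoherence: zero coupling and wide spread give r of order 1/sqrt(N)
  N2 <- 100
  omega2 <- 2 * pi * runif(N2, 25, 50)
  r_inc <- mean(replicate(5, trial_synchrony(
    simulate_trial(omega2, matrix(0, N2, N2), cfg), cfg)))
  expect_lt(r_inc, 3 / sqrt(N2))
})

test_that("phase-locking values behave as expected", {
  cfg <- trial_config()
  tt <- seq(0, 1, by = 0.001)
  ## constant offset: perfectly locked
  th <- cbind(2 * pi * 40 * tt, 2 * pi * 40 * tt + 1)
  P <- pairwise_plv(toy_trajectory(th), cfg)
  expect_equal(P, matrix(1, 2, 2), tolerance = 1e-9)
  ## fast incommensurate relative drift: PLV near zero
  th2 <- cbind(2 * pi * 40 * tt, 2 * pi * 47.3 * tt)
  P2 <- pairwise_plv(toy_trajectory(th2), cfg)
  expect_lt(P2[1, 2], 0.1)
  ## independent phases: Rayleigh scale sqrt(pi) / (2 sqrt(n))
  set.seed(33)
  n_sub <- cfg$subsample_points
  vals <- replicate(300, {
    th <- matrix(runif(2 * length(tt), 0, 2 * pi), ncol = 2)
    pairwise_plv(toy_trajectory(th), cfg)[1, 2]
  })
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(n_sub)), tolerance = 0.1)
})

test_that("sessions aggregate trials per condition and are reproducible", {
  sh <- sheet6()
  w <- weights6()
  K1 <- initial_coupling(sh)
  conds <- build_condition_grid(2, 2)
  cfg <- trial_config(substeps = 1)
  res <- run_session(sh, w, K1, conds, blocks = 2, config = cfg,
                     seed = 99, retain_plv = TRUE)
  expect_equal(nrow(res$trials), 2 * 4)
  expect_equal(length(res$plv), 8)
  expect_equal(dim(res$tongue$values), c(2, 2))
  expect_true(all(res$trials$r_mean >= 0 & res$trials$r_mean <= 1))
  ## tongue cells are block means of the matching trials
  agg <- with(res$trials, tapply(r_mean, list(zeta_level, rho_level), mean))
  expect_equal(unname(res$tongue$values), unname(as.matrix(agg)))
  res2 <- run_session(sh, w, K1, conds, blocks = 2, config = cfg, seed = 99)
  expect_identical(res$tongue$values, res2$tongue$values)
  ## different seed, different stimuli
  res3 <- run_session(sh, w, K1, conds, blocks = 2, config = cfg, seed = 100)
  expect_false(identical(res$tongue$values, res3$tongue$values))
})
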