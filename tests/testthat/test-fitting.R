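# Trajectory cost, R-squared, parameter fitting on synthetic strides.

test_that("cost of a solution against its own noiseless stride is ~0", {
  hop <- forward_hop()
  traj <- generate_fixture(hop, sigma = 0, seed = 1, velocities = "exact")
  cst <- trajectory_cost(hop, traj)
  expect_lt(as.numeric(cst), 1e-12)
  # all four channels at R^2 = 1
  for (ch in c("x", "y", "alpha_l", "alpha_r"))
    expect_equal(r_squared(hop, traj, ch), 1, tolerance = 1e-8)
})

test_that("a constant height offset contributes ~ delta^2 * T to the cost", {
  hop <- forward_hop()
  traj <- generate_fixture(hop, sigma = 0, seed = 1, velocities = "exact")
  delta <- 0.01
  traj$y <- traj$y + delta
  cst <- as.numeric(trajectory_cost(hop, traj))
  expect_equal(cst, delta^2 * max(traj$t), tolerance = 0.02)
})

test_that("the cost ignores the recording's horizontal origin", {
  hop <- forward_hop()
  traj <- generate_fixture(hop, sigma = 0, seed = 1, velocities = "exact")
  c0 <- as.numeric(trajectory_cost(hop, traj))
  traj$x <- traj$x + 12.3
  expect_equal(as.numeric(trajectory_cost(hop, traj)), c0,
               tolerance = 1e-10)
})

test_that("model = data mean gives R^2 = 0", {
  hop <- forward_hop()
  traj <- generate_fixture(hop, sigma = 0, seed = 1, velocities = "exact")
  # data y := mean + (model - mean)/2 makes SS_res equal SS_tot exactly
  traj2 <- traj
  mt <- gait_trajectory(hop, t_eval = traj$t)
  traj2$y <- mean(mt$y) + (mt$y - mean(mt$y)) / 2
  expect_equal(r_squared(hop, traj2, "y"), 0, tolerance = 1e-6)
  # zero-variance channel is flagged
  traj3 <- traj
  traj3$y <- rep(1.1, nrow(traj3))
  expect_warning(r2 <- r_squared(hop, traj3, "y"), "zero-variance")
  expect_true(is.na(r2))
})

test_that("noiseless self-fit recovers the generating parameters", {
  p_true <- slip_params(omega = 6.6, phi_l = 0.02, phi_r = 0.05)
  hop <- forward_hop()
  tr <- track_gait(hop, p_true)
  expect_true(tr$reached)
  sol_true <- tr$sol
  traj <- generate_fixture(sol_true, sigma = 0, seed = 7,
                           velocities = "exact")
  # start from 10% perturbed parameters, seeded at the true solution
  init <- find_gait_bvp(sol_true,
                        slip_params(omega = 6.6 * 1.02, phi_l = 0.017,
                                    phi_r = 0.056),
                        anchor = "stride_time", value = sol_true$T)
  expect_true(init$converged)
  fit <- fit_slip(traj, init, maxit = 200)
  expect_lt(abs(fit$par[["omega"]] - 6.6) / 6.6, 0.01)
  expect_lt(abs(fit$par[["phi_l"]] - 0.02), 0.01)
  expect_lt(abs(fit$par[["phi_r"]] - 0.05), 0.01)
  expect_lt(fit$cost, 1e-6)
  expect_true(all(fit$r_squared > 0.99))
  # methods work
  expect_named(coef(fit), c("omega", "phi_l", "phi_r"))
  expect_equal(nrow(predict(fit)), nrow(traj))
  expect_equal(dim(residuals(fit)), c(nrow(traj), 4L))
})
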