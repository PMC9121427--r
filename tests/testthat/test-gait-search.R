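# Periodic-gait search, the full constraint system, classification, metrics.

test_that("the gait system residual vanishes on known solutions and the solver is idempotent", {
  p <- nominal_params
  hop <- forward_hop()
  r <- gait_system_residual(hop$X, p)
  expect_true(attr(r, "ok"))
  expect_lt(sqrt(sum(r^2)), 1e-8)
  # re-solving from the solution returns the same solution
  g2 <- find_gait_bvp(hop, p, anchor = "energy", value = hop$energy)
  expect_true(g2$converged)
  expect_lt(max(abs(g2$X - hop$X)), 1e-7)
  # zero-speed seed residual is zero to solver tolerance
  vh <- vertical_hop(1.2, p)
  rv <- gait_system_residual(vh, p)
  expect_lt(sqrt(sum(rv^2)), 1e-8)
})

test_that("perturbed candidates re-converge (well-conditioned neighborhood)", {
  p <- nominal_params
  hop <- forward_hop()
  set.seed(3)
  X <- hop$X * (1 + 0.02 * runif(11, -1, 1))
  g <- find_gait_bvp(X, p, anchor = "energy", value = hop$energy)
  expect_true(g$converged)
  expect_equal(unname(g$s[2]), unname(hop$s[2]), tolerance = 1e-6)
})

test_that("single-shooting find_gait agrees with the full system on hops", {
  p <- nominal_params
  g <- find_gait(c(1.2, 0, 0, 0, 0, 0), p, anchor = "energy", value = 1.25)
  expect_true(g$converged)
  expect_equal(g$label, "hopping")
  expect_equal(g$energy, 1.25, tolerance = 1e-8)
  expect_lt(g$residual_norm, 1e-8)
})

test_that("classification reproduces the defining event patterns", {
  # hopping: synchronized legs
  expect_equal(classify_gait(list(tltd = .3, tllo = .6, trtd = .3,
                                  trlo = .6, T = 1)), "hopping")
  # skipping: overlapping but staggered stances, one aerial phase
  expect_equal(classify_gait(list(tltd = .4, tllo = .7, trtd = .2,
                                  trlo = .5, T = 1)), "skipping")
  # symmetric running: half-stride offset, two equal aerial phases
  expect_equal(classify_gait(list(tltd = .6, tllo = .8, trtd = .1,
                                  trlo = .3, T = 1)), "symmetric_running")
  # asymmetric running: two unequal aerial phases
  expect_equal(classify_gait(list(tltd = .55, tllo = .8, trtd = .1,
                                  trlo = .3, T = 1)), "asymmetric_running")
  # walking: no aerial phase (left stance wraps the stride boundary)
  expect_equal(classify_gait(list(tltd = .55, tllo = .3, trtd = .05,
                                  trlo = .6, T = 1)), "walking")
  # equality is tested before strict order: near-simultaneity is hopping
  expect_equal(classify_gait(list(tltd = .3001, tllo = .6, trtd = .3,
                                  trlo = .6003, T = 1), tol_t = 1e-3),
               "hopping")
  # degenerate: missing / out-of-range times
  expect_equal(classify_gait(list(tltd = NA, tllo = .6, trtd = .3,
                                  trlo = .6, T = 1)), "degenerate")
})

test_that("stride metrics follow their definitions", {
  tt <- list(tltd = 0.2, tllo = 0.6, trtd = 0.2, trlo = 0.6, T = 1)
  m <- slipgait:::stride_metrics(tt, stride_length = 2.5)
  expect_equal(m$duty_factor, 0.4)
  expect_equal(m$average_speed, 2.5)
  # zero-speed hop: zero stride length and average speed
  vh <- vertical_hop(1.2, nominal_params)
  expect_equal(vh$stride_length, 0, tolerance = 1e-8)
  expect_equal(vh$average_speed, 0, tolerance = 1e-8)
  # identity average speed = stride length / stride time on a real gait
  hop <- forward_hop()
  gm <- gait_metrics(hop)
  expect_equal(gm$average_speed, hop$stride_length / hop$T,
               tolerance = 1e-12)
})

test_that("left/right exchange symmetry of coupled solutions", {
  p <- nominal_params
  hop <- forward_hop()
  s_sw <- slipgait:::swap_legs_s(hop$s)
  X_sw <- c(s_sw, hop$X[9], hop$X[10], hop$X[7], hop$X[8], hop$X[11])
  r <- gait_system_residual(X_sw, p)
  expect_lt(sqrt(sum(r^2)), 1e-8)
})
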