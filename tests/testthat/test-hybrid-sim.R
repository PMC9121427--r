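# Event-driven stride integration and the apex return map.

test_that("ballistic flight from apex is exact and the event residual is tiny", {
  p <- nominal_params
  st <- simulate_stride(slip_state(y = 1.2), p, stop = "event",
                        record = TRUE)
  expect_equal(st$events$type[1], "touchdown")
  expect_equal(st$events$time[1], sqrt(2 * 0.2), tolerance = 1e-9)
  tr <- st$trajectory
  expect_lt(max(abs(tr$y - (1.2 - tr$t^2 / 2))), 1e-9)
  # event residual: y - lo cos(alpha) at the located touchdown
  se <- st$state_end
  expect_lt(abs(se$y - cos(se$alpha_l)), 1e-10)
})

test_that("vertical bounce duration matches the two-leg spring closed form", {
  p <- nominal_params
  st <- simulate_stride(slip_state(y = 1.2), p, stop = "stride")
  expect_equal(st$status, "periodic-candidate")
  # both legs land together: stiffness 2k oscillator about 1 - g/(2k)
  v <- sqrt(2 * 0.2)                       # contact speed
  keff <- 2 * p$k
  A <- sqrt(v^2 / keff + (p$g / keff)^2)
  theta <- acos((p$g / keff) / A)
  stance <- (2 * pi - 2 * theta) / sqrt(keff)
  lo_t <- st$times$tllo - st$times$tltd
  expect_equal(lo_t, stance, tolerance = 1e-7)
  expect_equal(st$t_end, 2 * sqrt(2 * 0.2) + stance, tolerance = 1e-7)
})

test_that("the zero-speed hop is a fixed point of the return map", {
  p <- nominal_params
  s0 <- c(1.2, 0, 0, 0, 0, 0)
  pm <- poincare_map(s0, p)
  expect_true(pm$ok)
  expect_lt(sqrt(sum((pm$s - s0)^2)), 1e-8)
  # touchdowns and liftoffs synchronized
  expect_equal(pm$times$tltd, pm$times$trtd, tolerance = 1e-9)
  expect_equal(pm$times$tllo, pm$times$trlo, tolerance = 1e-9)
  # small perturbation shifts event times continuously
  pm2 <- poincare_map(s0 + c(0, 1e-9, 0, 0, 0, 0), p)
  expect_lt(abs(pm2$times$tltd - pm$times$tltd), 1e-6)
})

test_that("energy and the stance constraint are conserved along strides", {
  p <- nominal_params
  hop <- forward_hop()
  st <- simulate_stride(apex_state(hop$s, p), p, stop = "stride")
  expect_equal(st$status, "periodic-candidate")
  expect_lt(st$energy_drift, 1e-6 * st$energy)
  expect_lt(st$constraint_max, 1e-8)
})

test_that("translation invariance: the reduced map ignores x0", {
  p <- nominal_params
  hop <- forward_hop()
  st1 <- simulate_stride(apex_state(hop$s, p), p, stop = "stride")
  sA <- apex_state(hop$s, p)
  sA$x <- 7.25
  st2 <- simulate_stride(sA, p, stop = "stride")
  expect_equal(reduce_state <- slipgait:::reduce_state(st1$state_end),
               slipgait:::reduce_state(st2$state_end), tolerance = 1e-9)
  expect_equal(st2$state_end$x - 7.25, st1$state_end$x, tolerance = 1e-8)
})

test_that("mirror symmetry: the reflected gait is also periodic", {
  p <- nominal_params   # phi_l = phi_r, so reflection + leg swap is a symmetry
  hop <- forward_hop()
  s_m <- slipgait:::mirror_s(hop$s)
  r <- periodicity_residual(s_m, p)
  expect_true(attr(r, "ok"))
  expect_lt(sqrt(sum(r^2)), 1e-7)
  X_m <- c(s_m, hop$X[9], hop$X[10], hop$X[7], hop$X[8], hop$X[11])
  rb <- gait_system_residual(X_m, p)
  expect_lt(sqrt(sum(rb^2)), 1e-8)
})

test_that("flight time-reversal recovers the state", {
  p <- nominal_params
  z0 <- slip_state(y = 1.3, alpha_l = 0.1, alpha_r = -0.2, xdot = 1,
                   ydot = 0, alphadot_l = 0.5, alphadot_r = -1)
  fw <- simulate_stride(z0, p, stop = "time", t_max = 0.3)
  se <- fw$state_end
  bk_state <- slip_state(x = se$x, y = se$y, alpha_l = se$alpha_l,
                         alpha_r = se$alpha_r, xdot = -se$xdot,
                         ydot = -se$ydot, alphadot_l = -se$alphadot_l,
                         alphadot_r = -se$alphadot_r)
  bk <- simulate_stride(bk_state, p, stop = "time", t_max = 0.3,
                        check_premature = FALSE)
  sb <- bk$state_end
  expect_equal(c(sb$x, sb$y, sb$alpha_l, sb$alpha_r),
               c(z0$x, z0$y, z0$alpha_l, z0$alpha_r), tolerance = 1e-9)
})

test_that("premature touchdown and falls are flagged", {
  p <- slip_params(phi_l = -0.6, phi_r = -0.6)
  # legs strongly swinging forward into the ground at contact
  st <- simulate_stride(slip_state(y = 1.4, alpha_l = -0.4, alpha_r = -0.4,
                                   xdot = 2, alphadot_l = 3,
                                   alphadot_r = 3), p, stop = "stride")
  expect_equal(st$status, "premature-touchdown")
  st2 <- simulate_stride(slip_state(y = 1.4, alpha_l = -0.4,
                                    alpha_r = -0.4, xdot = 2,
                                    alphadot_l = 3, alphadot_r = 3), p,
                         stop = "stride", check_premature = FALSE)
  expect_true(st2$status != "premature-touchdown")
})
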