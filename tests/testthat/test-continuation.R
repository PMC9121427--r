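# Branch continuation, Floquet machinery, transitions.

test_that("branches are ordered families of converged solutions", {
  br <- small_hop_branch()
  expect_gt(br$n, 10)
  expect_true(all(br$info$label == "hopping"))
  # every stored candidate satisfies the gait system
  set.seed(1)
  for (i in sample(br$n, 5)) {
    r <- gait_system_residual(br$X[i, ], nominal_params)
    expect_lt(sqrt(sum(r^2)), 1e-7)
  }
  # consecutive solutions differ by bounded arclength
  d <- sqrt(rowSums(diff(br$X)^2))
  expect_true(all(d < 0.5 + 1e-9))
})

test_that("branch retraceability: continuing back recovers the start", {
  br <- small_hop_branch()
  g_end <- slipgait:::build_gait_from_candidate(br$X[br$n, ],
                                                nominal_params,
                                                converged = TRUE,
                                                residual_norm = NA_real_)
  g0 <- find_gait_bvp(g_end, nominal_params, anchor = "energy",
                      value = br$info$E[1])
  expect_true(g0$converged)
  # the two branch halves are mirror images; compare up to reflection
  expect_equal(abs(unname(g0$s[2])), abs(br$info$xdot0[1]),
               tolerance = 1e-6)
})

test_that("monodromy has a unit multiplier and is step-size robust", {
  hop <- forward_hop()
  ev5 <- floquet_multipliers(hop, h = 1e-5)
  ev6 <- floquet_multipliers(hop, h = 1e-6)
  # exactly one multiplier within 1e-4 of +1 (conservative family direction)
  expect_equal(sum(abs(ev6 - 1) < 1e-4), 1)
  # spectra agree across steps
  expect_lt(max(abs(sort(Mod(ev5)) - sort(Mod(ev6)))), 1e-3)
  # leg-swap symmetry leaves the spectrum invariant
  s_sw <- slipgait:::swap_legs_s(hop$s)
  X_sw <- c(s_sw, hop$X[9], hop$X[10], hop$X[7], hop$X[8], hop$X[11])
  g_sw <- slipgait:::build_gait_from_candidate(X_sw, nominal_params,
                                               converged = TRUE,
                                               residual_norm = NA_real_)
  ev_sw <- floquet_multipliers(g_sw, h = 1e-6)
  expect_lt(max(abs(sort(Mod(ev_sw)) - sort(Mod(ev6)))), 1e-5)
})

test_that("a branch with no multiplier crossing yields no bifurcations", {
  br <- small_hop_branch()
  # restrict to a short low-speed stretch where the desynchronizing
  # multiplier stays well below +1
  keep <- which(abs(br$info$xdot0) < 2)
  sub <- br
  sub$X <- br$X[keep, , drop = FALSE]
  sub$S <- br$S[keep, , drop = FALSE]
  sub$info <- br$info[keep, ]
  sub$n <- length(keep)
  bifs <- detect_bifurcation(sub, nominal_params, stride_every = 5L)
  expect_length(bifs, 0)
})

test_that("timing-degeneracy search reports not-found for monotone gaps", {
  br <- small_hop_branch()
  # hopping has identically zero l-vs-r stagger; the l_td vs r_lo gap never
  # changes sign along this branch
  td <- locate_timing_degeneracy(br, nominal_params, gap = "l_td_r_lo")
  expect_true(is.null(td) || abs(attr(td, "gap")) < 1e-8)
})

test_that("parameter tracking carries a gait to uncoupled angles and back", {
  p <- nominal_params
  hop <- forward_hop()
  p_u <- slip_params(phi_l = -0.01, phi_r = 0)
  tr <- track_gait(hop, p_u)
  expect_true(tr$reached)
  expect_equal(tr$sol$label, "skipping")   # uncoupling staggers the legs
  back <- track_gait(tr$sol, p)
  expect_true(back$reached)
  expect_equal(back$sol$label, "hopping")
})
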