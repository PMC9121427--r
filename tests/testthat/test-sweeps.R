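# Sweep wrappers (cheap smoke at the nominal angle, reusing the cached
# structure; the full-range behavior is exercised by the acceptance tests).

test_that("the coupled sweep reproduces the nominal entry at phi = 0", {
  ns <- nominal_structure_cached()
  sw <- sweep_coupled(phis = 0, p_base = nominal_params, nominal = ns)
  expect_length(sw, 1)
  ent <- sw[[1]]
  expect_equal(ent$phi, 0)
  expect_equal(ent$hop$label, "hopping")
  expect_equal(ent$skip$label, "skipping")
  expect_false(is.null(ent$transition_low))
  # the tracked lower transition at phi = 0 is the nominal one
  expect_equal(unname(ent$transition_low$s[2]),
               unname(ns$skip_ar_transitions[[1]]$s[2]), tolerance = 1e-6)
})

test_that("the uncoupled sweep tracks solutions and transitions over a phi_l grid", {
  ns <- nominal_structure_cached()
  p <- nominal_params
  br <- ns$skip_ar
  isk <- which(br$info$label == "skipping")
  i0 <- isk[which.min(abs(br$info$xdot0[isk] - 7))]
  start <- slipgait:::build_gait_from_candidate(br$X[i0, ], p,
                                                converged = TRUE,
                                                residual_norm = NA_real_)
  sw <- sweep_uncoupled(phi_l_grid = c(-0.005, -0.01), phi_r = 0,
                        p_base = p, start = start,
                        transitions = ns$skip_ar_transitions[1])
  expect_length(sw$solutions, 2)
  ok <- !vapply(sw$solutions, is.null, logical(1))
  expect_true(any(ok))
  # uncoupling staggers the legs: only skipping and asymmetric running
  # remain feasible (the tracked point may slide between the two along the
  # uncoupled loop)
  for (g in sw$solutions[ok])
    expect_true(g$label %in% c("skipping", "asymmetric_running"))
  expect_true(nrow(sw$transitions) >= 1)
  expect_true(all(abs(sw$transitions$phi_r) < 1e-12))
})

test_that("print methods summarize gaits and branches", {
  hop <- forward_hop()
  expect_output(print(hop), "hopping")
  expect_output(print(hop$params), "omega")
  br <- small_hop_branch()
  expect_output(print(br), "solutions")
  expect_output(summary(hop), "hopping")
})
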