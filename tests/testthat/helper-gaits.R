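# Shared fixtures, built once per test run.

nominal_params <- slip_params()

# an exact zero-speed vertical hop at apex height 1.2
zero_hop <- function() vertical_hop(1.2, nominal_params)

# a forward hopping solution at apex speed 1 on the fundamental branch
# (slow enough that the apex foot clearance is positive, so event-driven
# and prescribed-times integration agree), cached across tests
forward_hop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      h0 <- seed_forward_hop(nominal_params)
      g <- find_gait_bvp(h0, nominal_params, anchor = "speed", value = 1)
      stopifnot(g$converged, g$s[1] - cos(g$s[3]) > 0)
      cache <<- g
    }
    cache
  }
})

# random stance states for the constraint-differentiation oracle; the
# stance leg angular velocity is set from the differentiated foot
# constraint so that alpha(t) and atan((xc - x)/y) agree to first order
random_stance_state <- function() {
  x <- runif(1, -0.5, 0.5); y <- runif(1, 0.7, 0.98)
  al <- runif(1, -0.5, 0.5)
  xd <- runif(1, -1, 2); yd <- runif(1, -1, 0.5)
  wl <- -(xd + yd * tan(al)) * cos(al)^2 / y
  slip_state(x = x, y = y, alpha_l = al, alpha_r = runif(1, -0.5, 0.5),
             xdot = xd, ydot = yd, alphadot_l = wl,
             alphadot_r = runif(1, -2, 2),
             mode_l = "stance", mode_r = "swing")
}

# a short hopping branch around speed 2, cached
small_hop_branch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- continue_branch(forward_hop(), nominal_params,
                                direction = "both", h0 = 0.05,
                                h_max = 0.4, max_points = 40,
                                speed_cap = 5)
    }
    cache
  }
})

# the full nominal gait structure (hop branch, skip/AR continuum with its
# transitions, running branch with the walk-run point), cached; this is the
# expensive shared fixture behind the acceptance tests
nominal_structure_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- nominal_gait_structure(nominal_params)
    cache
  }
})

# a skipping solution at jerboa-trial parameters, cached
jerboa_like_gait_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- jerboa_skipping_gait(nominal_params,
                                     nominal = nominal_structure_cached())
    cache
  }
})
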