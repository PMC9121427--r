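# Reduced coordinates on the flight-apex Poincare section.
#
# The section is ydot = 0 crossed from above with both legs in swing; by
# translation invariance x is dropped (x0 = 0), leaving the reduced state
# s = (y0, xdot0, alpha_l0, alphadot_l0, alpha_r0, alphadot_r0).

reduced_names <- c("y0", "xdot0", "alpha_l0", "alphadot_l0",
                   "alpha_r0", "alphadot_r0")

#' Build a flight-apex state from reduced section coordinates
#'
#' @param s numeric length 6: `(y0, xdot0, alpha_l0, alphadot_l0, alpha_r0,
#'   alphadot_r0)`.
#' @param p model parameters (used only for the foot-clearance check).
#' @return a [slip_state()] at the apex (`x = 0`, `ydot = 0`, both legs in
#'   swing).
#' @export
apex_state <- function(s, p = slip_params()) {
  p <- as_slip_params(p)
  slip_state(x = 0, y = s[1], alpha_l = s[3], alpha_r = s[5],
             xdot = s[2], ydot = 0, alphadot_l = s[4], alphadot_r = s[6])
}

reduce_state <- function(state) {
  c(state$y, state$xdot, state$alpha_l, state$alphadot_l,
    state$alpha_r, state$alphadot_r)
}

apex_valid <- function(s, p) {
  is.finite(s[1]) && s[1] > 0 &&
    s[1] - p$lo * cos(s[3]) > -1e-12 && s[1] - p$lo * cos(s[5]) > -1e-12
}

#' Apex-to-apex Poincare return map
#'
#' Simulates one full stride from the reduced apex state and re-reduces the
#' terminal apex.  Fixed points of this map are periodic gaits.
#'
#' @param s reduced apex state, see [apex_state()].
#' @param p model parameters.
#' @param ... passed to [simulate_stride()].
#' @return list with `s` (the mapped reduced state, `NA` on failure), `ok`,
#'   `status`, `T`, `times`, `stride_length`, `energy`, and the `stride`
#'   object itself.
#' @export
poincare_map <- function(s, p = slip_params(), ...) {
  p <- as_slip_params(p)
  if (!apex_valid(s, p))
    return(list(s = rep(NA_real_, 6), ok = FALSE, status = "invalid-start",
                T = NA_real_, times = NULL, stride_length = NA_real_,
                energy = NA_real_, stride = NULL))
  st <- simulate_stride(apex_state(s, p), p, stop = "stride", ...)
  ok <- st$status == "periodic-candidate"
  list(s = if (ok) reduce_state(st$state_end) else rep(NA_real_, 6),
       ok = ok, status = st$status, T = st$t_end, times = st$times,
       stride_length = st$stride_length, energy = st$energy, stride = st)
}

#' Periodicity residual of an apex candidate
#'
#' The shooting residual `P(s) - s` of the apex return map in reduced
#' coordinates: periodicity of height and leg angles plus all velocities.
#' Horizontal position is cyclic (the stride length is bookkept separately),
#' and the four touchdown/liftoff leg-length conditions are satisfied
#' identically by the event-driven integration, so a zero of this residual is
#' a root of the full periodicity system.
#'
#' @inheritParams poincare_map
#' @return numeric length 6 with attributes `ok`, `status`, `times`, `T`,
#'   `stride_length`, `energy`.  On a failed stride the residual is a large
#'   penalty with `ok = FALSE`.
#' @export
periodicity_residual <- function(s, p = slip_params(), ...) {
  pm <- poincare_map(s, p, ...)
  r <- if (pm$ok) pm$s - s else rep(1e6, 6)
  attr(r, "ok") <- pm$ok
  attr(r, "status") <- pm$status
  attr(r, "times") <- pm$times
  attr(r, "T") <- pm$T
  attr(r, "stride_length") <- pm$stride_length
  attr(r, "energy") <- pm$energy
  attr(r, "amp_max") <- if (!is.null(pm$stride)) pm$stride$amp_max else NA_real_
  r
}

#' Apex energy of a reduced state
#'
#' Total energy on the section: `xdot0^2/2 + g*y0` (the apex is in flight
#' with `ydot = 0`, so no elastic term arises).
#' @inheritParams poincare_map
#' @return energy \[m*g*lo\].
#' @export
apex_energy <- function(s, p = slip_params()) {
  p <- as_slip_params(p)
  0.5 * p$m * s[2]^2 + p$m * p$g * s[1]
}

# leg-swap operator on reduced states
swap_legs_s <- function(s) s[c(1, 2, 5, 6, 3, 4)]

# mirror operator on reduced states: reverse direction of travel
mirror_s <- function(s) c(s[1], -s[2], -s[5], -s[6], -s[3], -s[4])
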