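#' Construct a hybrid model state
#'
#' A full continuous state of the biped: center-of-mass position `(x, y)`
#' \[lo\], leg angles from the downward vertical (counterclockwise positive)
#' \[rad\], their time derivatives, and the per-leg contact mode with the
#' stationary foot anchor `xc_*` (defined only in stance; recomputed from the
#' holonomic foot constraint `xc = x + y*tan(alpha)` when missing).
#'
#' @param x,y COM position \[lo\].
#' @param alpha_l,alpha_r leg angles \[rad\].
#' @param xdot,ydot COM velocities \[sqrt(g*lo)\].
#' @param alphadot_l,alphadot_r leg angular velocities \[sqrt(g/lo)\].
#' @param mode_l,mode_r `"swing"` or `"stance"`.
#' @param xc_l,xc_r stance foot anchors \[lo\] (optional; derived if `NA`).
#' @return An object of class `slip_state`.
#' @export
slip_state <- function(x = 0, y = 1, alpha_l = 0, alpha_r = 0,
                       xdot = 0, ydot = 0, alphadot_l = 0, alphadot_r = 0,
                       mode_l = "swing", mode_r = "swing",
                       xc_l = NA_real_, xc_r = NA_real_) {
  mode_l <- match.arg(mode_l, c("swing", "stance"))
  mode_r <- match.arg(mode_r, c("swing", "stance"))
  s <- list(x = x, y = y, alpha_l = alpha_l, alpha_r = alpha_r,
            xdot = xdot, ydot = ydot,
            alphadot_l = alphadot_l, alphadot_r = alphadot_r,
            mode_l = mode_l, mode_r = mode_r, xc_l = xc_l, xc_r = xc_r)
  for (leg in c("l", "r")) {
    if (s[[paste0("mode_", leg)]] == "stance") {
      a <- s[[paste0("alpha_", leg)]]
      if (y <= 0 || abs(a) >= pi / 2)
        stop("stance leg requires y > 0 and |alpha| < pi/2")
      if (is.na(s[[paste0("xc_", leg)]]))
        s[[paste0("xc_", leg)]] <- x + y * tan(a)
    }
  }
  structure(s, class = "slip_state")
}

# internal: state <-> kernel vector (x, y, al, ar, vx, vy, wl, wr)
state_to_z <- function(s) {
  c(s$x, s$y, s$alpha_l, s$alpha_r, s$xdot, s$ydot, s$alphadot_l, s$alphadot_r)
}
state_modes <- function(s) {
  c(ifelse(s$mode_l == "stance", 1L, 0L), ifelse(s$mode_r == "stance", 1L, 0L))
}
state_anchors <- function(s) c(s$xc_l, s$xc_r)

z_to_state <- function(z, modes, anchors = c(NA_real_, NA_real_)) {
  # no validity checks: terminal states of failed strides may be degenerate
  structure(list(x = z[1], y = z[2], alpha_l = z[3], alpha_r = z[4],
                 xdot = z[5], ydot = z[6], alphadot_l = z[7],
                 alphadot_r = z[8],
                 mode_l = if (modes[1] == 1) "stance" else "swing",
                 mode_r = if (modes[2] == 1) "stance" else "swing",
                 xc_l = anchors[1], xc_r = anchors[2]),
            class = "slip_state")
}

#' @export
print.slip_state <- function(x, ...) {
  cat(sprintf("slip_state: COM (%.4g, %.4g), vel (%.4g, %.4g)\n",
              x$x, x$y, x$xdot, x$ydot))
  cat(sprintf("  left : alpha %.4g, alphadot %.4g, %s\n",
              x$alpha_l, x$alphadot_l, x$mode_l))
  cat(sprintf("  right: alpha %.4g, alphadot %.4g, %s\n",
              x$alpha_r, x$alphadot_r, x$mode_r))
  invisible(x)
}

leg_field <- function(s, what, leg) s[[paste0(what, "_", leg)]]

#' Instantaneous leg length
#'
#' A swing leg is massless and uncompressed, so its length is exactly `lo`;
#' a stance leg spans the foot anchor to the COM, `y / cos(alpha)`.
#'
#' @param state a [slip_state()].
#' @param leg `"l"` or `"r"`.
#' @param p model parameters.
#' @return leg length \[lo\].
#' @export
leg_length <- function(state, leg = c("l", "r"), p = slip_params()) {
  leg <- match.arg(leg)
  p <- as_slip_params(p)
  if (leg_field(state, "mode", leg) == "swing") return(p$lo)
  a <- leg_field(state, "alpha", leg)
  if (state$y <= 0 || abs(a) >= pi / 2)
    stop("geometric degeneracy: stance leg with y <= 0 or |alpha| >= pi/2")
  state$y / cos(a)
}

#' Net leg force on the body
#'
#' Each stance leg contributes a linear-spring force of magnitude
#' `k * (lo - l)` directed from the foot anchor toward the COM; swing legs
#' are massless and contribute nothing.
#'
#' @inheritParams leg_length
#' @return list with components `Fx`, `Fy` \[m*g\].
#' @export
net_force <- function(state, p = slip_params()) {
  p <- as_slip_params(p)
  Fx <- 0; Fy <- 0
  for (leg in c("l", "r")) {
    if (leg_field(state, "mode", leg) == "stance") {
      l <- leg_length(state, leg, p)
      if (l < 0) stop("negative leg length")
      a <- leg_field(state, "alpha", leg)
      f <- p$k * (p$lo - l)
      Fx <- Fx - f * sin(a)
      Fy <- Fy + f * cos(a)
    }
  }
  list(Fx = Fx, Fy = Fy)
}

#' Swing-leg angular acceleration
#'
#' Passive swing dynamics: the pendulum coupling of the massless leg (with an
#' infinitesimal foot mass) to the accelerating body, plus the torsional
#' restoring term that drives the leg toward its neutral angle `phi` at
#' frequency `omega`.  In ballistic flight (`yddot = -g`) the body terms
#' cancel and the leg oscillates harmonically about `phi` at exactly `omega`.
#'
#' @param state a [slip_state()] with the leg in swing.
#' @param body_accel numeric length 2, `c(xddot, yddot)`.
#' @param leg `"l"` or `"r"`.
#' @param p model parameters.
#' @return angular acceleration \[g/lo\].
#' @export
swing_leg_accel <- function(state, body_accel, leg = c("l", "r"),
                            p = slip_params()) {
  leg <- match.arg(leg)
  p <- as_slip_params(p)
  stopifnot(leg_field(state, "mode", leg) == "swing")
  a <- leg_field(state, "alpha", leg)
  phi <- leg_field(p, "phi", leg)
  -(body_accel[1] * cos(a) + (p$g + body_accel[2]) * sin(a)) / p$lo -
    p$omega^2 * (a - phi)
}

#' Stance-leg angular acceleration
#'
#' Obtained by differentiating the holonomic foot constraint
#' `xc - x - y*tan(alpha) = 0` twice in time, so the stance leg angle remains
#' kinematically consistent with the COM motion.
#'
#' @inheritParams swing_leg_accel
#' @return angular acceleration \[g/lo\].
#' @export
stance_leg_accel <- function(state, body_accel, leg = c("l", "r")) {
  leg <- match.arg(leg)
  stopifnot(leg_field(state, "mode", leg) == "stance")
  a <- leg_field(state, "alpha", leg)
  w <- leg_field(state, "alphadot", leg)
  y <- state$y
  if (y <= 0) stop("terminal event: y <= 0 in stance")
  if (abs(a) >= pi / 2) stop("geometric degeneracy: |alpha| >= pi/2 in stance")
  -2 * w^2 * tan(a) - 2 * w * state$ydot / y -
    (body_accel[1] + body_accel[2] * tan(a)) * cos(a)^2 / y
}

#' Touchdown reset of a leg's angular velocity
#'
#' At touchdown of leg `i` (foot height `y - lo*cos(alpha_i)` reaching zero
#' from above) the leg switches to stance.  The COM state is unchanged (the
#' legs are massless); the touching leg's angular velocity is replaced by the
#' unique value that makes the foot-anchor velocity zero, obtained by
#' differentiating the foot constraint once, and the anchor is set from the
#' constraint itself.
#'
#' @param state_minus the pre-touchdown [slip_state()].
#' @param leg `"l"` or `"r"`.
#' @return the post-touchdown `slip_state`.
#' @export
touchdown_reset <- function(state_minus, leg = c("l", "r")) {
  leg <- match.arg(leg)
  s <- state_minus
  a <- leg_field(s, "alpha", leg)
  if (abs(a) >= pi / 2) stop("touchdown with |alpha| >= pi/2")
  wplus <- -(s$xdot + s$ydot * tan(a)) * cos(a)^2 / s$y
  s[[paste0("alphadot_", leg)]] <- wplus
  s[[paste0("mode_", leg)]] <- "stance"
  s[[paste0("xc_", leg)]] <- s$x + s$y * tan(a)
  s
}

#' Total mechanical energy
#'
#' Kinetic plus gravitational potential energy of the body plus the elastic
#' energy of any compressed stance leg.  At a flight apex this reduces to
#' `m*xdot^2/2 + m*g*y`.  The model is conservative: along any simulated
#' stride (touchdown resets included) this quantity is constant to
#' integration tolerance.
#'
#' @inheritParams leg_length
#' @return energy \[m*g*lo\].
#' @export
total_energy <- function(state, p = slip_params()) {
  p <- as_slip_params(p)
  E <- 0.5 * p$m * (state$xdot^2 + state$ydot^2) + p$m * p$g * state$y
  for (leg in c("l", "r")) {
    if (leg_field(state, "mode", leg) == "stance") {
      l <- leg_length(state, leg, p)
      E <- E + 0.5 * p$k * (p$lo - l)^2
    }
  }
  E
}
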