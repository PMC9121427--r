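status_labels <- c("0" = "periodic-candidate", "1" = "fell",
                   "2" = "premature-touchdown", "3" = "event-overflow",
                   "4" = "tmax-reached", "5" = "numerical-failure",
                   "6" = "invalid-start")

#' Simulate the hybrid dynamics over one stride
#'
#' Event-driven adaptive Runge-Kutta (Dormand-Prince 4/5) integration of the
#' biped from a given state, chaining flight and stance phases across
#' touchdown and liftoff events.  Touchdown applies the constraint-consistent
#' angular-velocity reset; events are located by root refinement to a
#' residual below about `1e-12` on the event function.
#'
#' Stopping rules:
#' * `"stride"` (default): stop at the first flight apex (`ydot` crossing 0
#'   from above with both legs in swing) after every leg has touched down and
#'   lifted off at least once.  This is the apex-to-apex Poincare return.
#' * `"apex"`: stop at the first flight apex.
#' * `"event"`: stop at the first touchdown/liftoff (single-phase
#'   integration).
#' * `"time"`: run to `t_max`.
#'
#' A touchdown while the leg is still rotating in the direction of travel
#' (`sign(xdot) * alphadot > 0` at contact) marks the stride
#' `"premature-touchdown"` and stops it; such solutions are treated as
#' degenerate throughout.  A stride is `"fell"` when `y` reaches 0 or a
#' stance leg reaches `|alpha| >= pi/2`.
#'
#' @param state a [slip_state()] (for stop modes `"stride"`/`"apex"` usually
#'   a flight apex: `ydot = 0`, both legs swinging).
#' @param p model parameters ([slip_params()]).
#' @param stop stopping rule, see Details.
#' @param t_max integration time limit \[sqrt(lo/g)\].
#' @param max_events maximum number of contact events before the stride is
#'   declared an event overflow (guards chattering).
#' @param n_cross for `stop = "crossing"`: stop at the n-th zero of `ydot`
#'   in any contact mode (the half-period point of reversible orbits).
#' @param rtol,atol integration tolerances.
#' @param t_eval optional increasing times at which to sample the trajectory
#'   exactly (the integrator lands on them).
#' @param record keep the accepted integration steps as a trajectory.
#' @param check_premature apply the premature-touchdown termination rule.
#' @param premature_wtol anterior angular-rate threshold \[sqrt(g/lo)\] above
#'   which a touchdown counts as premature.  Genuine premature contacts come
#'   with order-one anterior rates and velocity resets; the small default
#'   keeps grazing contacts and the infinitesimally anterior touchdowns
#'   found right at branch-birth bifurcations from being misflagged.
#' @return An object of class `slip_stride`: list with `status`, `t_end`,
#'   `state_end`, `events` (data frame), `times` (touchdown/liftoff times and
#'   stride time `T`, `NA` when not realized), `energy`, `energy_drift`,
#'   `constraint_max`, `amp_max`, `stride_length`, and `trajectory` /
#'   `samples` data frames.
#' @examples
#' # ballistic drop onto both legs: the zero-speed vertical hop
#' st <- simulate_stride(slip_state(y = 1.2), slip_params())
#' st$status
#' @export
simulate_stride <- function(state, p = slip_params(),
                            stop = c("stride", "apex", "event", "time",
                                     "crossing"),
                            t_max = 50, max_events = 8, n_cross = 1,
                            rtol = 1e-9, atol = 1e-11, t_eval = NULL,
                            record = FALSE, check_premature = TRUE,
                            premature_wtol = 0.05) {
  stop <- match.arg(stop)
  p <- as_slip_params(p)
  stop_mode <- match(stop, c("stride", "apex", "event", "time",
                             "crossing")) - 1L
  res <- slip_stride_cpp(state_to_z(state), state_modes(state),
                         state_anchors(state), par_vec(p), stop_mode,
                         t_max, as.integer(max_events), rtol, atol,
                         if (is.null(t_eval)) numeric(0) else as.numeric(t_eval),
                         premature_wtol, isTRUE(check_premature),
                         isTRUE(record), as.integer(n_cross))
  status <- unname(status_labels[as.character(res$status)])
  if (stop == "time" && res$status == 4L) status <- "periodic-candidate"
  ev <- data.frame(time = res$ev_time,
                   leg = ifelse(res$ev_leg < 0, NA_character_,
                                c("l", "r")[pmax(res$ev_leg, 0) + 1L]),
                   type = c("touchdown", "liftoff", "apex")[res$ev_type + 1L],
                   stringsAsFactors = FALSE)
  first_ev <- function(leg, type) {
    i <- which(ev$leg == leg & ev$type == type)
    if (length(i)) ev$time[i[1]] else NA_real_
  }
  times <- list(tltd = first_ev("l", "touchdown"),
                tllo = first_ev("l", "liftoff"),
                trtd = first_ev("r", "touchdown"),
                trlo = first_ev("r", "liftoff"),
                T = res$t_end)
  traj <- NULL
  col_names <- c("t", "x", "y", "alpha_l", "alpha_r", "xdot", "ydot",
                 "alphadot_l", "alphadot_r", "mode_l", "mode_r")
  if (!is.null(res$steps)) {
    traj <- as.data.frame(res$steps)
    names(traj) <- col_names
  }
  samples <- NULL
  if (!is.null(res$dense)) {
    samples <- as.data.frame(res$dense)
    names(samples) <- col_names
  }
  out <- list(status = status, t_end = res$t_end,
              state_end = z_to_state(res$z_end, res$modes_end,
                                     res$anchors_end),
              events = ev, times = times,
              energy = res$energy0, energy_drift = res$energy_drift,
              constraint_max = res$constraint_max, amp_max = res$amp_max,
              stride_length = res$z_end[1] - state$x,
              trajectory = traj, samples = samples, params = p)
  class(out) <- "slip_stride"
  out
}

#' Integrate a single hybrid phase
#'
#' Runs the continuous dynamics from `state` until the first
#' touchdown/liftoff event (or `t_max`), returning the stride object of the
#' segment and the triggering event.
#'
#' @inheritParams simulate_stride
#' @return a `slip_stride` restricted to one phase; component `event` holds
#'   the triggering event row (or `NULL` if time ran out).
#' @export
integrate_phase <- function(state, p = slip_params(), t_max = 50,
                            rtol = 1e-9, atol = 1e-11, record = FALSE) {
  st <- simulate_stride(state, p, stop = "event", t_max = t_max,
                        rtol = rtol, atol = atol, record = record)
  contact <- st$events[st$events$type != "apex", , drop = FALSE]
  st$event <- if (nrow(contact)) contact[1, ] else NULL
  st
}

#' @export
print.slip_stride <- function(x, ...) {
  cat(sprintf("slip_stride: status %s, t_end %.6g\n", x$status, x$t_end))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    %-10s %-2s t = %.6g\n", x$events$type[i],
                  ifelse(is.na(x$events$leg[i]), "-", x$events$leg[i]),
                  x$events$time[i]))
  }
  cat(sprintf("  energy %.6g (drift %.2e), constraint max %.2e\n",
              x$energy, x$energy_drift, x$constraint_max))
  invisible(x)
}

#' @export
plot.slip_stride <- function(x, which = c("com", "angles"), ...) {
  which <- match.arg(which)
  tr <- x$trajectory
  if (is.null(tr)) tr <- x$samples
  if (is.null(tr)) stop("stride was simulated without record = TRUE or t_eval")
  if (which == "com") {
    plot(tr$t, tr$y, type = "l", xlab = "t [sqrt(lo/g)]", ylab = "y [lo]",
         main = "COM height", ...)
  } else {
    matplot(tr$t, cbind(tr$alpha_l, tr$alpha_r), type = "l", lty = 1,
            col = c("navy", "skyblue"), xlab = "t [sqrt(lo/g)]",
            ylab = "alpha [rad]", main = "leg angles", ...)
    legend("topright", c("left", "right"), col = c("navy", "skyblue"),
           lty = 1, bty = "n")
  }
  invisible(x)
}
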