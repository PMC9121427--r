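# The full periodicity system with event times as unknowns.
#
# Single shooting over an event-detecting stride gives a residual that is
# only piecewise smooth: whenever a candidate's contact sequence reorders,
# the detected events jump.  The boundary-value formulation used for the
# actual gait search instead treats the four touchdown/liftoff times and the
# stride time as unknowns, integrates fixed-mode segments between them (no
# event detection), and imposes the four leg-length contact conditions at
# the event times plus state periodicity at T.  That residual is smooth in
# all 11 unknowns - including across event-time collisions, which is what
# makes walking<->running and skipping<->asymmetric-running timing
# degeneracies regular points of the solver.
#
# Candidate layout: X = (y0, xdot0, alpha_l0, alphadot_l0, alpha_r0,
# alphadot_r0, t_ltd, t_llo, t_rtd, t_rlo, T), anchored at a flight apex
# (x0 = 0, ydot0 = 0).

candidate_names <- c("y0", "xdot0", "alpha_l0", "alphadot_l0", "alpha_r0",
                     "alphadot_r0", "tltd", "tllo", "trtd", "trlo", "T")

as_candidate <- function(x) {
  if (inherits(x, "slip_gait")) {
    tt <- x$times
    X <- c(as.numeric(x$s), tt$tltd, tt$tllo, tt$trtd, tt$trlo, tt$T)
  } else X <- as.numeric(x)
  if (length(X) != 11 || any(!is.finite(X)))
    stop("candidate must be 11 finite numbers (reduced state, 4 event times, T)")
  setNames(X, candidate_names)
}

# advance a raw kernel state by dt under fixed contact modes; returns the
# end state with the segment's max swing amplitude as attribute
advance_fixed <- function(z, modes, anchors, dt, p, rtol, atol) {
  if (dt < 0) return(NULL)
  if (dt == 0) return(structure(z, amp = max(abs(z[3:4])), scuff = 0L))
  res <- slip_stride_cpp(z, modes, anchors, par_vec(p), 3L, dt, 100L,
                         rtol, atol, numeric(0), 0.05, FALSE, FALSE, 1L,
                         FALSE)
  if (res$status != 4L || !all(is.finite(res$z_end))) return(NULL)
  structure(res$z_end, amp = res$amp_max, scuff = res$anterior_scuff)
}

eq6_penalty <- function(status) {
  out <- rep(1e6, 11)
  attr(out, "ok") <- FALSE
  attr(out, "status") <- status
  out
}

#' Periodicity residual of a full gait candidate (event times as unknowns)
#'
#' Evaluates the gait-finding constraint system on a candidate consisting of
#' the reduced apex state, the four touchdown/liftoff times and the stride
#' time: state periodicity at `T` (height, leg angles, all velocities; the
#' horizontal position is cyclic and bookkept as stride length) plus the
#' four contact conditions `y(t) - lo*cos(alpha(t)) = 0` at the event times.
#' Integration runs segment-wise with the contact modes prescribed by the
#' candidate's event ordering, so the residual is smooth in every unknown.
#'
#' @param X candidate: numeric length 11 `(y0, xdot0, alpha_l0, alphadot_l0,
#'   alpha_r0, alphadot_r0, tltd, tllo, trtd, trlo, T)`, or a `slip_gait`.
#' @param p model parameters.
#' @param rtol,atol integration tolerances.
#' @return numeric length 11 (7 periodicity + 4 contact residuals) with
#'   attributes `ok`, `stride_length`, `energy`.
#' @export
gait_system_residual <- function(X, p = slip_params(), rtol = 1e-9,
                                 atol = 1e-11) {
  p <- as_slip_params(p)
  X <- as_candidate(X)
  s <- X[1:6]; tev <- X[7:10]; T <- X[11]
  if (T <= 0 || any(tev < 0) || any(tev > T))
    return(eq6_penalty("times-out-of-range"))
  if (X[7] >= X[8] || X[9] >= X[10])
    return(eq6_penalty("liftoff-before-touchdown"))
  if (s[1] <= 0) return(eq6_penalty("invalid-start"))
  ev <- data.frame(time = tev, leg = c(1L, 1L, 2L, 2L),
                   type = c("td", "lo", "td", "lo"))
  ev <- ev[order(ev$time), ]
  z <- c(0, s[1], s[3], s[5], s[2], 0, s[4], s[6])
  modes <- c(0L, 0L)
  anchors <- c(NA_real_, NA_real_)
  t_cur <- 0
  g_ev <- setNames(numeric(4), c("l_td", "l_lo", "r_td", "r_lo"))
  amp <- max(abs(z[3:4]))
  td_anterior <- -Inf   # max over touchdowns of sign(xdot)*alphadot^-
  scuff <- 0L           # premature (earlier-than-solved) anterior contacts
  for (k in seq_len(4)) {
    z <- advance_fixed(z, modes, anchors, ev$time[k] - t_cur, p, rtol, atol)
    if (is.null(z)) return(eq6_penalty("segment-failure"))
    amp <- max(amp, attr(z, "amp"))
    scuff <- scuff + attr(z, "scuff")
    t_cur <- ev$time[k]
    leg <- ev$leg[k]
    a <- z[2 + leg]
    if (abs(a) >= pi / 2 || z[2] <= 0)
      return(eq6_penalty("geometric-degeneracy"))
    key <- paste0(c("l", "r")[leg], "_", ev$type[k])
    g_ev[key] <- z[2] - p$lo * cos(a)
    if (ev$type[k] == "td") {
      # premature-touchdown diagnostic: anterior rotation at contact
      dir <- if (z[5] > 1e-8) 1 else if (z[5] < -1e-8) -1 else 0
      td_anterior <- max(td_anterior, dir * z[6 + leg])
      # constraint-consistent angular-velocity reset, foot anchored
      z[6 + leg] <- -(z[5] + z[6] * tan(a)) * cos(a)^2 / z[2]
      anchors[leg] <- z[1] + z[2] * tan(a)
      modes[leg] <- 1L
    } else {
      modes[leg] <- 0L
      anchors[leg] <- NA_real_
    }
  }
  z <- advance_fixed(z, modes, anchors, T - t_cur, p, rtol, atol)
  if (is.null(z)) return(eq6_penalty("segment-failure"))
  amp <- max(amp, attr(z, "amp"))
  scuff <- scuff + attr(z, "scuff")
  out <- c(z[2] - s[1],            # height periodicity
           z[3] - s[3], z[4] - s[5],  # leg angles
           z[5] - s[2], z[6] - 0,     # COM velocities (apex: ydot(T) = 0)
           z[7] - s[4], z[8] - s[6],  # leg angular velocities
           g_ev)
  attr(out, "ok") <- TRUE
  attr(out, "status") <- "evaluated"
  attr(out, "stride_length") <- z[1]
  attr(out, "energy") <- apex_energy(s, p)
  attr(out, "amp_max") <- amp
  attr(out, "td_anterior") <- td_anterior
  attr(out, "anterior_scuff") <- scuff
  attr(out, "times") <- list(tltd = X[7], tllo = X[8], trtd = X[9],
                             trlo = X[10], T = T)
  out
}

# anchor closures used by the Eq.-6 solver and continuation
eq6_anchor_value <- function(X, anchor, p) {
  switch(anchor,
    energy = apex_energy(X[1:6], p),
    speed = X[2],
    height = X[1],
    stride_time = X[11],
    NA_real_)
}

#' Find a periodic gait from a full candidate (state + event times)
#'
#' Damped Gauss-Newton on [gait_system_residual()] with one anchor closing
#' the conservative family's free direction.  This is the robust gait-search
#' entry point: because the event times are unknowns, seeds assembled from
#' published tables (state, timings, stride time) or from neighboring
#' solutions converge reliably even when a naive event-driven stride from
#' the seed would realize a different contact sequence.
#'
#' Admissibility follows the termination rules of the original analysis: a
#' solution whose solved touchdown arrives with the leg still rotating in
#' the direction of travel (premature touchdown) is flagged degenerate.
#' Swing-foot height between events is unconstrained (the template-model
#' scuffing convention); [stride_consistent()] reports whether an
#' event-detecting stride also reproduces the solution.
#'
#' @param seed a `slip_gait`, or numeric length 11 (see
#'   [gait_system_residual()]).
#' @param p model parameters.
#' @param anchor,value family anchor: `"energy"`, `"speed"`, `"height"`,
#'   `"stride_time"` or `"none"` (minimal-norm projection).
#' @param tol,maxit Gauss-Newton controls.
#' @param ... passed to [gait_system_residual()] consumers (unused).
#' @return a `slip_gait` (with `$X` holding the converged candidate).
#' @export
find_gait_bvp <- function(seed, p = slip_params(),
                          anchor = c("energy", "speed", "height",
                                     "stride_time", "none"),
                          value = NULL, tol = default_gn_tol, maxit = 60,
                          ...) {
  anchor <- match.arg(anchor)
  p <- as_slip_params(p)
  X0 <- as_candidate(seed)
  if (anchor != "none" && is.null(value))
    value <- eq6_anchor_value(X0, anchor, p)
  Fres <- function(X) {
    r <- gait_system_residual(X, p)
    if (anchor != "none") {
      out <- c(r, eq6_anchor_value(X, anchor, p) - value)
      attributes(out) <- attributes(r)
      out
    } else r
  }
  if (anchor == "none") {
    # phase 1: minimal-norm projection onto the manifold (coarse - the
    # family direction is only numerically null, limiting the attainable
    # residual); phase 2: polish with a pseudo-arclength border along the
    # computed null direction, which is always well-posed.
    # aggressive pseudo-inverse truncation here: the family direction is
    # numerically near-null and must be projected out, not amplified
    cs <- gn_solve(Fres, X0, tol = max(tol, 1e-6), maxit = maxit,
                   svd_rtol = 3e-7)
    if (cs$converged) {
      J <- fd_jacobian(Fres, cs$u, cs$residual)
      if (!is.null(J)) {
        tau <- svd(J)$v[, length(cs$u)]
        u_st <- cs$u
        Fb <- function(X) {
          r <- gait_system_residual(X, p)
          out <- c(r, sum(tau * (X - u_st)))
          attributes(out) <- attributes(r)
          out
        }
        cs2 <- gn_solve(Fb, cs$u, tol = tol, maxit = 20)
        if (cs2$converged) cs <- cs2
      }
    }
  } else {
    cs <- gn_solve(Fres, X0, tol = tol, maxit = maxit)
  }
  build_gait_from_candidate(cs$u, p, converged = cs$converged,
                            residual_norm = cs$norm, niter = cs$niter,
                            solver_status = cs$status, ...)
}

# package a candidate as slip_gait; admissibility follows the original
# study's rules (no premature touchdown, bounded swing amplitude), with no
# constraint on swing-foot height between events
build_gait_from_candidate <- function(X, p, converged, residual_norm,
                                      niter = NA_integer_,
                                      solver_status = "converged",
                                      premature_wtol = 0.05,
                                      amp_cap = 1.7, ...) {
  X <- as_candidate(X)
  s <- X[1:6]
  times <- list(tltd = X[7], tllo = X[8], trtd = X[9], trlo = X[10],
                T = X[11])
  r <- gait_system_residual(X, p)
  sl <- attr(r, "stride_length") %||% NA_real_
  lab <- classify_gait(times)
  met <- stride_metrics(times, sl)
  td_ant <- attr(r, "td_anterior") %||% NA_real_
  amp_max <- attr(r, "amp_max") %||% NA_real_
  premature <- is.finite(td_ant) && td_ant > premature_wtol
  admissible <- isTRUE(converged) && isTRUE(attr(r, "ok")) && !premature &&
    (!is.finite(amp_max) || amp_max <= amp_cap)
  if (isTRUE(converged) && !admissible) lab <- "degenerate"
  structure(list(
    s = setNames(as.numeric(s), reduced_names), params = p, times = times,
    T = X[11], label = lab, energy = apex_energy(s, p), apex_speed = s[2],
    stride_length = sl, average_speed = met$average_speed,
    duty_factor = met$duty_factor, residual_norm = residual_norm,
    converged = isTRUE(converged), niter = niter,
    solver_status = solver_status, amp_max = amp_max,
    td_anterior = td_ant, premature = premature,
    status = attr(r, "status") %||% "bvp",
    admissible = admissible, X = X, floquet = NULL), class = "slip_gait")
}

#' Does an event-detecting stride reproduce a periodic solution?
#'
#' The gait search tolerates a swing foot transiently below ground between
#' contact events (the template-model convention).  This helper re-simulates
#' a solution with full event detection and reports whether the realized
#' contact sequence matches the solution's event times - i.e. whether the
#' gait is also scuff-free.
#'
#' @param sol a converged `slip_gait`.
#' @param time_tol event-time agreement tolerance \[sqrt(lo/g)\].
#' @param ... passed to [simulate_stride()].
#' @return logical.
#' @export
stride_consistent <- function(sol, time_tol = 1e-5, ...) {
  stopifnot(inherits(sol, "slip_gait"))
  st <- tryCatch(simulate_stride(apex_state(sol$s, sol$params), sol$params,
                                 stop = "stride", ...),
                 error = function(e) NULL)
  if (is.null(st) || st$status != "periodic-candidate") return(FALSE)
  tt <- unlist(st$times)
  if (any(!is.finite(tt))) return(FALSE)
  max(abs(tt - unlist(sol$times))) < max(time_tol, time_tol * sol$T)
}

# Event-detection-free evaluation of the apex return map: for a given
# reduced apex state the four contact times and the stride time are slaved
# to the state by solving the four leg-length conditions plus the terminal
# apex condition ydot(T) = 0 (warm-started from a reference solution's
# times).  This evaluates the same Poincare map as the event-driven
# simulator but stays defined for solutions whose swing foot scuffs between
# events, so monodromy matrices can be computed anywhere on a branch.
poincare_map_bvp <- function(s, times_ref, p, rtol = 1e-9, atol = 1e-11,
                             tol = 1e-11, maxit = 12) {
  s <- as.numeric(s)
  tfun <- function(tv) {
    X <- c(s, tv)
    r <- gait_system_residual(X, p, rtol = rtol, atol = atol)
    if (!isTRUE(attr(r, "ok"))) return(NULL)
    # contact conditions are rows 8:11; ydot(T) residual is row 5
    list(g = c(r[8:11], r[5]), r = r)
  }
  tv <- as.numeric(times_ref)
  for (it in seq_len(maxit)) {
    f0 <- tfun(tv)
    if (is.null(f0)) return(NULL)
    if (max(abs(f0$g)) < tol) break
    J <- matrix(NA_real_, 5, 5)
    for (j in 1:5) {
      h <- 1e-8 * max(1, abs(tv[j]))
      fj <- tfun(tv + h * (1:5 == j))
      if (is.null(fj)) return(NULL)
      J[, j] <- (fj$g - f0$g) / h
    }
    step <- tryCatch(solve(J, -f0$g), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
    tv <- tv + step
    if (tv[5] <= 0) return(NULL)
  }
  f0 <- tfun(tv)
  if (is.null(f0) || max(abs(f0$g)) > 1e-8) return(NULL)
  r <- f0$r
  # reconstruct the mapped reduced state from the periodicity residual rows
  sp <- c(r[1] + s[1], r[4] + s[2], r[2] + s[3], r[6] + s[4],
          r[3] + s[5], r[7] + s[6])
  list(s = sp, times = tv)
}

#' Sample the trajectory of a periodic solution
#'
#' Integrates the solution's stride segment-by-segment (contact modes
#' prescribed by its event times, no event detection - the same convention
#' as the gait search) and returns the state sampled at the requested
#' times.
#'
#' @param sol a converged `slip_gait` (or candidate vector).
#' @param t_eval sample times in `[0, T]`; default a uniform grid.
#' @param n grid size when `t_eval` is missing.
#' @param p model parameters (from `sol` if available).
#' @param rtol,atol integration tolerances.
#' @return data frame with columns `t, x, y, alpha_l, alpha_r, xdot, ydot,
#'   alphadot_l, alphadot_r, mode_l, mode_r`.
#' @export
gait_trajectory <- function(sol, t_eval = NULL, n = 201, p = NULL,
                            rtol = 1e-9, atol = 1e-11) {
  if (inherits(sol, "slip_gait") && is.null(p)) p <- sol$params
  p <- as_slip_params(p %||% slip_params())
  X <- as_candidate(sol)
  T <- X[11]
  if (is.null(t_eval)) t_eval <- seq(0, T, length.out = n)
  t_eval <- sort(as.numeric(t_eval))
  stopifnot(all(t_eval >= -1e-12), all(t_eval <= T + 1e-9))
  ev <- data.frame(time = X[7:10], leg = c(1L, 1L, 2L, 2L),
                   type = c("td", "lo", "td", "lo"))
  ev <- ev[order(ev$time), ]
  bounds <- c(ev$time, T)
  z <- c(0, X[1], X[3], X[5], X[2], 0, X[4], X[6])
  modes <- c(0L, 0L)
  anchors <- c(NA_real_, NA_real_)
  t_cur <- 0
  rows <- list()
  pv <- par_vec(p)
  for (k in seq_len(5)) {
    t_next <- bounds[k]
    sel <- t_eval >= t_cur - 1e-12 & t_eval < t_next - 1e-12
    loc <- t_eval[sel] - t_cur
    res <- slip_stride_cpp(z, modes, anchors, pv, 3L, t_next - t_cur, 100L,
                           rtol, atol, loc, 0.05, FALSE, FALSE, 1L, FALSE)
    if (res$status != 4L && (t_next - t_cur) > 1e-14)
      stop("trajectory sampling failed in segment ", k)
    if (length(loc)) {
      d <- as.data.frame(res$dense)
      d[, 1] <- d[, 1] + t_cur
      rows[[length(rows) + 1]] <- d
    }
    if ((t_next - t_cur) > 1e-14) z <- res$z_end
    t_cur <- t_next
    if (k == 5) break
    leg <- ev$leg[k]
    a <- z[2 + leg]
    if (ev$type[k] == "td") {
      z[6 + leg] <- -(z[5] + z[6] * tan(a)) * cos(a)^2 / z[2]
      anchors[leg] <- z[1] + z[2] * tan(a)
      modes[leg] <- 1L
    } else {
      modes[leg] <- 0L
      anchors[leg] <- NA_real_
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, 11)
  out <- as.data.frame(out)
  names(out) <- c("t", "x", "y", "alpha_l", "alpha_r", "xdot", "ydot",
                  "alphadot_l", "alphadot_r", "mode_l", "mode_r")
  if (any(t_eval > T - 1e-12)) {
    out <- rbind(out, data.frame(t = T, x = z[1], y = z[2], alpha_l = z[3],
                                 alpha_r = z[4], xdot = z[5], ydot = z[6],
                                 alphadot_l = z[7], alphadot_r = z[8],
                                 mode_l = modes[1], mode_r = modes[2]))
  }
  out
}
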