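# Neutral-leg-swing-angle parameter sweeps.
#
# Solutions are carried through parameter space by warm-started minimal-norm
# re-solves of the gait system (the anchor is left open so the tracked
# solution can slide along its shrinking branch), with adaptive step halving
# in the parameter.  Existence boundaries are the parameter values at which
# tracking fails irrecoverably; gait-transition points are carried as
# bordered systems (periodicity + zero timing gap).

#' Track a periodic solution to other model parameters
#'
#' Re-solves the gait system while stepping `phi_l`, `phi_r` (and optionally
#' `omega`) from the solution's parameters toward a target, warm-starting
#' each step from the previous solution with the family anchor left open
#' (minimal-norm projection).  Steps halve on failure.
#'
#' @param sol a converged `slip_gait`.
#' @param p_target target parameters.
#' @param step initial parameter step (fraction of the total change).
#' @param min_step smallest fraction before giving up.
#' @param require_admissible drop solutions flagged degenerate (premature
#'   touchdown), treating them as tracking failure.
#' @param anchor family anchor held during tracking: `"none"` (minimal-norm,
#'   the tracked point may slide along its branch) or `"speed"` /
#'   `"energy"` / `"height"` (held at `value`, keeping the tracked point
#'   from drifting onto neighboring families).
#' @param value anchor value (default: the start solution's).
#' @param ... passed to [find_gait_bvp()].
#' @return list with `sol` (last converged `slip_gait`), `reached`
#'   (logical), `frac` (fraction of the parameter path covered).
#' @export
track_gait <- function(sol, p_target, step = 0.25, min_step = 1e-3,
                       require_admissible = TRUE, anchor = "none",
                       value = NULL, ...) {
  stopifnot(inherits(sol, "slip_gait"), isTRUE(sol$converged))
  p0 <- sol$params
  p_target <- as_slip_params(p_target)
  if (anchor != "none" && is.null(value))
    value <- eq6_anchor_value(as_candidate(sol), anchor, p0)
  mix <- function(f) slip_params(
    k = p0$k + f * (p_target$k - p0$k),
    omega = p0$omega + f * (p_target$omega - p0$omega),
    phi_l = p0$phi_l + f * (p_target$phi_l - p0$phi_l),
    phi_r = p0$phi_r + f * (p_target$phi_r - p0$phi_r),
    m = p0$m, lo = p0$lo, g = p0$g)
  f <- 0
  h <- step
  cur <- sol
  while (f < 1 - 1e-12) {
    h <- min(h, 1 - f)
    g <- find_gait_bvp(cur, mix(f + h), anchor = anchor, value = value, ...)
    ok <- g$converged && (!require_admissible || isTRUE(g$admissible))
    if (ok) {
      f <- f + h
      cur <- g
      h <- min(h * 1.6, 1 - f + 1e-16)
      if (h <= 0) break
    } else {
      h <- h / 2
      if (h < min_step)
        return(list(sol = cur, reached = FALSE, frac = f))
    }
  }
  list(sol = cur, reached = TRUE, frac = 1)
}

#' Existence boundary of a gait family along the coupled neutral angle
#'
#' Carries a gait family as `phi_l = phi_r` moves from the start solution's
#' value toward `phi_limit` and returns the last neutral angle at which any
#' representative survives, bisected to `tol`.  Representatives are held at
#' fixed apex-speed anchors (one tracked copy per entry of `speeds`), which
#' prevents the minimal-norm tracker from drifting onto neighboring
#' zero-speed families as the branch deforms; the family counts as existing
#' at an angle while at least one anchored representative converges to an
#' admissible solution there.
#'
#' @param sol a converged `slip_gait` at coupled neutral angles.
#' @param phi_limit the search limit \[rad\].
#' @param tol boundary resolution \[rad\].
#' @param speeds apex-speed anchors for the tracked representatives
#'   (default: the start solution's speed).
#' @param ... passed to [track_gait()].
#' @return list with `phi` (boundary estimate), `sols` (surviving
#'   representatives at the boundary), `hit_limit`.
#' @export
phi_existence_boundary <- function(sol, phi_limit, tol = 5e-3,
                                   speeds = NULL, ...) {
  p0 <- sol$params
  stopifnot(isTRUE(all.equal(p0$phi_l, p0$phi_r)))
  pset <- function(phi) slip_params(k = p0$k, omega = p0$omega,
                                    phi_l = phi, phi_r = phi,
                                    m = p0$m, lo = p0$lo, g = p0$g)
  if (is.null(speeds)) speeds <- sol$s[2]
  sols <- list()
  for (v in speeds) {
    g <- find_gait_bvp(sol, p0, anchor = "speed", value = v)
    if (g$converged && isTRUE(g$admissible)) sols[[length(sols) + 1]] <- g
  }
  if (!length(sols)) sols <- list(sol)
  lo <- p0$phi_l            # known to exist
  hi <- phi_limit           # suspected not to
  carry <- function(phi) {
    out <- list()
    for (g in sols) {
      tr <- track_gait(g, pset(phi), anchor = "speed", value = g$s[2], ...)
      if (tr$reached) out[[length(out) + 1]] <- tr$sol
    }
    if (length(out)) out else NULL
  }
  res <- carry(hi)
  if (!is.null(res))
    return(list(phi = hi, sols = res, hit_limit = TRUE))
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    res <- carry(mid)
    if (!is.null(res)) {
      lo <- mid
      sols <- res
    } else hi <- mid
  }
  list(phi = (lo + hi) / 2, sols = sols, hit_limit = FALSE)
}

# bordered solve: periodicity + zero timing gap at fixed parameters
solve_transition <- function(Xseed, p, gap = c("l_td_r_lo", "r_td_l_lo"),
                             maxit = 30) {
  gap <- match.arg(gap)
  gidx <- if (gap == "l_td_r_lo") c(7L, 10L) else c(9L, 8L)
  Ffun <- branch_residual_bvp(p)
  G <- function(u) {
    r <- Ffun(u)
    o <- c(r, u[gidx[1]] - u[gidx[2]])
    attributes(o) <- attributes(r)[c("ok", "status")]
    o
  }
  cs <- gn_solve(G, as.numeric(Xseed), maxit = maxit)
  if (!cs$converged) return(NULL)
  sol <- build_gait_from_candidate(cs$u, p, converged = TRUE,
                                   residual_norm = cs$norm)
  attr(sol, "gap") <- cs$u[gidx[1]] - cs$u[gidx[2]]
  attr(sol, "type") <- "timing-degeneracy"
  sol
}

#' Carry a skip/asymmetric-run transition point across neutral angles
#'
#' Steps `phi_l` (and `phi_r` for coupled sweeps) from the transition's
#' parameters to a target, re-solving the bordered transition system
#' (periodicity plus zero timing gap) with warm starts and adaptive halving.
#'
#' @param tp a transition `slip_gait` (from [locate_timing_degeneracy()] or
#'   [all_timing_degeneracies()]).
#' @param p_target target parameters.
#' @param gap which timing gap defines the transition.
#' @param step,min_step stepping control (fractions of the parameter path).
#' @param require_admissible reject transitions flagged degenerate.
#' @return list with `sol` (transition at the last reached parameters),
#'   `reached`, `frac`.
#' @export
track_transition <- function(tp, p_target, gap = c("l_td_r_lo",
                                                   "r_td_l_lo"),
                             step = 0.25, min_step = 1e-3,
                             require_admissible = TRUE) {
  gap <- match.arg(gap)
  p0 <- tp$params
  p_target <- as_slip_params(p_target)
  mix <- function(f) slip_params(
    k = p0$k + f * (p_target$k - p0$k),
    omega = p0$omega + f * (p_target$omega - p0$omega),
    phi_l = p0$phi_l + f * (p_target$phi_l - p0$phi_l),
    phi_r = p0$phi_r + f * (p_target$phi_r - p0$phi_r),
    m = p0$m, lo = p0$lo, g = p0$g)
  f <- 0
  h <- step
  cur <- tp
  while (f < 1 - 1e-12) {
    h <- min(h, 1 - f)
    g <- solve_transition(as_candidate(cur), mix(f + h), gap = gap)
    if (!is.null(g) && (!require_admissible || isTRUE(g$admissible))) {
      f <- f + h
      cur <- g
      h <- min(h * 1.6, 1)
    } else {
      h <- h / 2
      if (h < min_step) return(list(sol = cur, reached = FALSE, frac = f))
    }
  }
  list(sol = cur, reached = TRUE, frac = 1)
}

#' Coupled neutral-leg-swing-angle sweep
#'
#' For each coupled value `phi_l = phi_r` in `phis`, carries a hopping
#' solution, the skipping branch switch, and the lower
#' skipping/asymmetric-running transition from the nominal structure, and
#' records the per-angle results.
#'
#' @param phis coupled neutral angles to visit \[rad\].
#' @param p_base base parameters (nominal `k`, `omega`).
#' @param nominal a precomputed [nominal_gait_structure()] (computed if
#'   missing).
#' @param trace_branches also trace the full hopping branch at each angle.
#' @param ... passed to [continue_branch()] when tracing.
#' @return list with one element per angle: `phi`, `hop` (tracked hopping
#'   `slip_gait` or NULL), `hop_branch` (optional), `skip` (tracked skipping
#'   solution), `transition_low` (tracked lower skip-AR transition), each
#'   NULL where tracking failed.
#' @export
sweep_coupled <- function(phis, p_base = slip_params(), nominal = NULL,
                          trace_branches = FALSE, ...) {
  p_base <- as_slip_params(p_base)
  if (is.null(nominal))
    nominal <- nominal_gait_structure(p_base, with_running = FALSE)
  hop_ref <- mid_branch_gait(nominal$hop, p_base)
  skip_ref <- first_label_gait(nominal$skip_ar, p_base, "skipping")
  tr_ref <- if (length(nominal$skip_ar_transitions))
    nominal$skip_ar_transitions[[1]] else NULL
  pset <- function(phi) slip_params(k = p_base$k, omega = p_base$omega,
                                    phi_l = phi, phi_r = phi)
  out <- lapply(phis, function(phi) {
    pt <- pset(phi)
    hop <- if (!is.null(hop_ref)) {
      tr <- track_gait(hop_ref, pt)
      if (tr$reached) tr$sol else NULL
    }
    skip <- if (!is.null(skip_ref)) {
      tr <- track_gait(skip_ref, pt)
      if (tr$reached) tr$sol else NULL
    }
    tlow <- if (!is.null(tr_ref)) {
      tr <- track_transition(tr_ref, pt, gap = attr_gap_of(tr_ref))
      if (tr$reached) tr$sol else NULL
    }
    hb <- if (trace_branches && !is.null(hop))
      continue_branch(hop, pt, direction = "both", ...) else NULL
    list(phi = phi, hop = hop, hop_branch = hb, skip = skip,
         transition_low = tlow)
  })
  names(out) <- sprintf("phi=%g", phis)
  out
}

attr_gap_of <- function(tp) {
  # which gap closed at this transition point
  X <- as_candidate(tp)
  if (abs(X[7] - X[10]) < abs(X[9] - X[8])) "l_td_r_lo" else "r_td_l_lo"
}

mid_branch_gait <- function(branch, p, speed = 2) {
  if (is.null(branch) || branch$n == 0) return(NULL)
  i <- which.min(abs(branch$info$xdot0 - speed))
  build_gait_from_candidate(branch$X[i, ], p, converged = TRUE,
                            residual_norm = NA_real_)
}

first_label_gait <- function(branch, p, label) {
  if (is.null(branch) || branch$n == 0) return(NULL)
  i <- which(branch$info$label == label)
  if (!length(i)) return(NULL)
  build_gait_from_candidate(branch$X[i[ceiling(length(i) / 2)], ], p,
                            converged = TRUE, residual_norm = NA_real_)
}

#' Uncoupled neutral-leg-swing-angle sweep
#'
#' With `phi_r` held fixed, steps `phi_l` over a grid and records the
#' tracked skipping/asymmetric-running solution and the
#' skip/asymmetric-running transition points (the only feasible gaits once
#' the legs are uncoupled).
#'
#' @param phi_l_grid left neutral angles to visit \[rad\].
#' @param phi_r fixed right neutral angle \[rad\].
#' @param p_base base parameters.
#' @param start a converged solution at coupled `phi_l = phi_r` used as the
#'   tracking origin (a skipping solution from the coupled structure).
#' @param transitions transition points at the coupled origin to carry
#'   along (list of transition `slip_gait`s).
#' @return list with `solutions` (per grid value, `slip_gait` or NULL) and
#'   `transitions` (data frame: phi_l, speed, gap type) collecting every
#'   transition successfully tracked to each grid value.
#' @export
sweep_uncoupled <- function(phi_l_grid, phi_r = 0, p_base = slip_params(),
                            start = NULL, transitions = list()) {
  p_base <- as_slip_params(p_base)
  pset <- function(phl) slip_params(k = p_base$k, omega = p_base$omega,
                                    phi_l = phl, phi_r = phi_r)
  sols <- vector("list", length(phi_l_grid))
  names(sols) <- sprintf("phi_l=%g", phi_l_grid)
  rows <- list()
  cur <- start
  curs_tr <- transitions
  for (k in seq_along(phi_l_grid)) {
    pt <- pset(phi_l_grid[k])
    if (!is.null(cur)) {
      tr <- track_gait(cur, pt)
      if (tr$reached) {
        cur <- tr$sol
        sols[[k]] <- tr$sol
      }
    }
    curs_tr <- lapply(curs_tr, function(tp) {
      if (is.null(tp)) return(NULL)
      tt <- track_transition(tp, pt, gap = attr_gap_of(tp))
      if (tt$reached) tt$sol else NULL
    })
    for (tp in curs_tr) {
      if (is.null(tp)) next
      rows[[length(rows) + 1]] <-
        data.frame(phi_l = phi_l_grid[k], phi_r = phi_r,
                   speed = unname(tp$s[2]), gap = attr_gap_of(tp),
                   stringsAsFactors = FALSE)
    }
  }
  list(solutions = sols,
       transitions = if (length(rows)) do.call(rbind, rows)
       else data.frame(phi_l = numeric(0), phi_r = numeric(0),
                       speed = numeric(0), gap = character(0)))
}

#' Existence boundary with mid-branch reseeding
#'
#' Steps the coupled neutral angle in increments of `dphi`, carrying a set
#' of speed-anchored representatives of the family.  When every
#' representative fails at a step, the full branch is re-traced at the last
#' surviving angle and fresh representatives are drawn from its quartiles
#' before retrying - this follows families whose speed range drifts or
#' shrinks as the neutral angle changes.  The boundary is the last angle
#' with any surviving representative, refined to `tol`.
#'
#' @param sol a converged `slip_gait` at coupled neutral angles.
#' @param phi_limit search limit \[rad\].
#' @param dphi angle step \[rad\].
#' @param tol boundary resolution \[rad\].
#' @param label_match keep only solutions whose label contains this regular
#'   expression (e.g. `"running"`); `NULL` accepts any non-degenerate gait.
#' @param max_points branch-trace budget for reseeding.
#' @param speed_cap continuation speed cap.
#' @param coupled vary `phi_l = phi_r` together (default) or `phi_l` only
#'   (uncoupled sweeps, `phi_r` held at the start solution's value).
#' @param speeds additional apex-speed anchors for the initial
#'   representative set.
#' @param ... passed to [find_gait_bvp()].
#' @return list with `phi`, `sols`, `hit_limit`.
#' @export
phi_branch_boundary <- function(sol, phi_limit, dphi = 0.05, tol = 0.01,
                                label_match = NULL, max_points = 200,
                                speed_cap = 30, coupled = TRUE,
                                speeds = NULL, ...) {
  p0 <- sol$params
  if (coupled) stopifnot(isTRUE(all.equal(p0$phi_l, p0$phi_r)))
  pset <- function(phi) slip_params(k = p0$k, omega = p0$omega,
                                    phi_l = phi,
                                    phi_r = if (coupled) phi else p0$phi_r,
                                    m = p0$m, lo = p0$lo, g = p0$g)
  ok_sol <- function(g) {
    g$converged && isTRUE(g$admissible) &&
      (is.null(label_match) || grepl(label_match, g$label))
  }
  carry1 <- function(g, phi) {
    g2 <- find_gait_bvp(g, pset(phi), anchor = "speed", value = g$s[2], ...)
    if (ok_sol(g2)) g2 else NULL
  }
  reseed <- function(g) {
    br <- tryCatch(continue_branch(g, g$params, direction = "both",
                                   h0 = 0.05, h_max = 0.5,
                                   max_points = max_points,
                                   speed_cap = speed_cap),
                   error = function(e) NULL)
    if (is.null(br) || br$n < 3) return(list(g))
    keep <- if (is.null(label_match)) seq_len(br$n)
    else which(grepl(label_match, br$info$label))
    if (!length(keep)) return(list(g))
    qs <- keep[unique(pmax(1, round(stats::quantile(seq_along(keep),
                                                    c(.25, .5, .75)))))]
    out <- lapply(qs, function(i)
      build_gait_from_candidate(br$X[i, ], g$params, converged = TRUE,
                                residual_norm = NA_real_))
    c(out, list(g))
  }
  dir <- sign(phi_limit - p0$phi_l)
  phi <- p0$phi_l
  seeds <- list(sol)
  if (!is.null(speeds)) {
    extra <- lapply(speeds, function(v) {
      g <- find_gait_bvp(sol, p0, anchor = "speed", value = v, ...)
      if (ok_sol(g)) g else NULL
    })
    seeds <- c(seeds, Filter(Negate(is.null), extra))
  }
  step <- dphi
  while (dir * (phi_limit - phi) > tol) {
    phi_next <- phi + dir * min(step, dir * (phi_limit - phi))
    nxt <- Filter(Negate(is.null), lapply(seeds, carry1, phi = phi_next))
    if (!length(nxt)) {
      # reseed from the branch at the current angle and retry once
      seeds2 <- unique(c(unlist(lapply(seeds[seq_len(min(2, length(seeds)))],
                                       reseed), recursive = FALSE)))
      nxt <- Filter(Negate(is.null), lapply(seeds2, carry1, phi = phi_next))
      if (length(nxt)) seeds <- seeds2
    }
    if (length(nxt)) {
      phi <- phi_next
      seeds <- nxt
      step <- dphi
    } else {
      step <- step / 2
      if (step < tol)
        return(list(phi = phi, sols = seeds, hit_limit = FALSE))
    }
  }
  list(phi = phi, sols = seeds, hit_limit = dir * (phi_limit - phi) <= tol)
}

#' Trace a gait-transition curve through parameter space
#'
#' Pseudo-arclength continuation of the bordered transition system
#' (periodicity + zero timing gap) with the left neutral angle `phi_l`
#' freed as a 12th unknown and `phi_r` held fixed.  The transition point's
#' locus through the uncoupled parameter space is a one-dimensional curve
#' that may fold in `phi_l`; this tracer follows it through folds, which is
#' how the full catalogue of skip/asymmetric-run transitions across a
#' neutral-angle window (speeds from near zero up to the fastest branches)
#' is collected.
#'
#' @param tp a transition `slip_gait` (zero timing gap) at the starting
#'   parameters.
#' @param gap which timing gap defines the transition (default: the one
#'   closed at `tp`).
#' @param phi_l_range stop when `phi_l` leaves this interval.
#' @param speed_range stop when the apex speed leaves this interval.
#' @param direction initial direction of `phi_l` (`+1`, `-1`, or `"both"`).
#' @param h0,h_max,max_points arclength stepping control.
#' @return data frame with one row per traced transition: `phi_l`, `phi_r`,
#'   `speed`, `gap`, `admissible`, plus the candidate columns.
#' @export
transition_curve <- function(tp, gap = NULL, phi_l_range = c(-0.5, 0.5),
                             speed_range = c(-1, 31),
                             direction = "both", h0 = 0.02, h_max = 0.25,
                             max_points = 400) {
  stopifnot(inherits(tp, "slip_gait"))
  if (is.null(gap)) gap <- attr_gap_of(tp)
  gidx <- if (gap == "l_td_r_lo") c(7L, 10L) else c(9L, 8L)
  p0 <- tp$params
  pset <- function(phl) slip_params(k = p0$k, omega = p0$omega,
                                    phi_l = phl, phi_r = p0$phi_r,
                                    m = p0$m, lo = p0$lo, g = p0$g)
  Ffun <- function(u) {
    r <- gait_system_residual(u[1:11], pset(u[12]))
    out <- c(r, u[gidx[1]] - u[gidx[2]])
    attributes(out) <- attributes(r)[c("ok", "status", "amp_max",
                                       "td_anterior")]
    out
  }
  u0 <- c(as_candidate(tp), p0$phi_l)
  stop_fun <- function(u, a) {
    if (u[12] < phi_l_range[1] || u[12] > phi_l_range[2])
      return("phi-range")
    if (u[2] < speed_range[1] || u[2] > speed_range[2])
      return("speed-range")
    NULL
  }
  dirs <- if (identical(direction, "both")) c(1, -1) else direction
  rows <- list()
  for (d in dirs) {
    cc <- continue_curve(Ffun, u0, h0 = h0, h_max = h_max,
                         max_points = max_points,
                         orient = function(tau, u)
                           if (sign(tau[12]) == d || tau[12] == 0) 1 else -1,
                         stop_fun = stop_fun, closed = TRUE)
    if (is.null(cc$U)) next
    for (i in seq_len(nrow(cc$U))) {
      u <- cc$U[i, ]
      X <- u[1:11]
      g <- build_gait_from_candidate(X, pset(u[12]), converged = TRUE,
                                     residual_norm = NA_real_)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(phi_l = u[12], phi_r = p0$phi_r, speed = X[2],
                   gap = gap, admissible = isTRUE(g$admissible),
                   label = g$label, termination = cc$termination),
        as.data.frame(t(X)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phi_l = numeric(0))
  rownames(out) <- NULL
  out
}
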