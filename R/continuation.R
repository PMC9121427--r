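# Pseudo-arclength predictor-corrector continuation.
#
# The periodic solutions of the conservative biped form one-dimensional
# manifolds ("branches") as the total energy varies.  Branches are traced in
# the full candidate space of the gait system (reduced apex state + event
# times + stride time, see gait_system_residual): that residual is smooth in
# every unknown, including across event-time collisions, so the tracer
# passes walking<->running and skipping<->asymmetric-running timing
# degeneracies without losing the corrector.  Each accepted solution is
# verified against an event-detecting stride; a solution whose realized
# contact sequence no longer matches its candidate times (foot grazing,
# premature touchdown, fall) terminates the branch, which reproduces the
# numerical-search termination rules of the original study.

continue_curve <- function(Ffun, u0, h0 = 0.02, h_min = 1e-7, h_max = 0.4,
                           max_points = 2000, tol = default_gn_tol,
                           fd_step = 1e-7, tangent0 = NULL, orient = NULL,
                           stop_fun = NULL, closed = TRUE, step_max = 0.5) {
  # land exactly on the manifold first
  st0 <- gn_solve(Ffun, u0, tol = tol, step_max = step_max)
  if (!st0$converged)
    return(list(U = NULL, attrs = NULL, termination = "seed-failure",
                closed = FALSE, status = st0$status))
  u <- st0$u
  n <- length(u)
  J <- fd_jacobian(Ffun, u, st0$residual, fd_step)
  if (is.null(J))
    return(list(U = matrix(u, 1), attrs = list(attributes(st0$residual)),
                termination = "jacobian-failure", closed = FALSE))
  tau <- svd(J)$v[, n]
  if (!is.null(tangent0) && sum(tau * tangent0) < 0) tau <- -tau
  if (!is.null(orient)) tau <- tau * orient(tau, u)

  U <- matrix(u, nrow = 1)
  attrs <- list(attributes(st0$residual))
  termination <- "max-points"
  is_closed <- FALSE
  h <- h0
  last_status <- NULL
  i <- 1
  while (i < max_points) {
    ok_step <- FALSE
    while (h >= h_min) {
      u_pred <- u + h * tau
      G <- function(v) {
        r <- Ffun(v)
        out <- c(r, sum(tau * (v - u_pred)))
        attributes(out) <- attributes(r)[c("ok", "status", "times", "T",
                                           "stride_length", "energy",
                                           "amp_max", "td_anterior",
                                           "anterior_scuff")]
        out
      }
      cs <- gn_solve(G, u_pred, tol = tol, maxit = 12, step_max = step_max)
      if (cs$converged && sqrt(sum((cs$u - u)^2)) > 1e-12) {
        ok_step <- TRUE
        break
      }
      last_status <- cs$status
      h <- h / 2
    }
    if (!ok_step) {
      termination <- last_status %||% "corrector-failure"
      break
    }
    u_new <- cs$u
    tau_new <- (u_new - u) / sqrt(sum((u_new - u)^2))
    u <- u_new
    tau <- tau_new
    U <- rbind(U, u)
    attrs[[length(attrs) + 1]] <- attributes(cs$residual)
    i <- i + 1
    if (!is.null(stop_fun)) {
      reason <- stop_fun(u, attrs[[length(attrs)]])
      if (!is.null(reason)) {
        termination <- reason
        break
      }
    }
    if (closed && i > 10) {
      d0 <- sqrt(sum((u - U[1, ])^2))
      if (d0 < 0.75 * h) {
        termination <- "closed-loop"
        is_closed <- TRUE
        break
      }
    }
    if (cs$niter <= 3) h <- min(h * 1.4, h_max)
  }
  list(U = U, attrs = attrs, termination = termination, closed = is_closed)
}

fd_jacobian <- function(Ffun, u, r0 = NULL, fd_step = 1e-7) {
  if (is.null(r0)) r0 <- Ffun(u)
  if (!isTRUE(attr(r0, "ok"))) return(NULL)
  n <- length(u)
  J <- matrix(NA_real_, length(r0), n)
  for (j in seq_len(n)) {
    h <- fd_step * max(1, abs(u[j]))
    rj <- Ffun(u + h * (seq_len(n) == j))
    if (!isTRUE(attr(rj, "ok"))) {
      rj <- Ffun(u - h * (seq_len(n) == j))
      if (!isTRUE(attr(rj, "ok"))) return(NULL)
      J[, j] <- (r0 - rj) / h
    } else J[, j] <- (rj - r0) / h
  }
  J
}

# residual closure for a gait branch in candidate space
branch_residual_bvp <- function(p, rtol = 1e-9, atol = 1e-11) {
  force(p)
  function(u) gait_system_residual(u, p, rtol = rtol, atol = atol)
}

# single-shooting residual closure (reduced apex coordinates), optionally in
# the leg-synchronized subspace; used by the bootstrap helpers
branch_residual <- function(p, symmetric = FALSE, ...) {
  expand <- if (symmetric) function(u) c(u[1:2], u[3], u[4], u[3], u[4])
  else identity
  function(u) {
    r <- periodicity_residual(expand(u), p, ...)
    out <- if (symmetric) r[1:4] else r
    attributes(out) <- attributes(r)[c("ok", "status", "times", "T",
                                       "stride_length", "energy")]
    attr(out, "amp_max") <- attr(r, "amp_max")
    out
  }
}

# admissibility of an accepted continuation point, from the gait-system
# residual diagnostics (the original study's termination rules)
candidate_stop_reason <- function(u, a, speed_cap, amp_cap,
                                  premature_wtol = 0.05) {
  if (abs(u[2]) > speed_cap) return("speed-cap")
  am <- a$amp_max
  if (!is.null(am) && is.finite(am) && am > amp_cap)
    return("swing-amplitude")
  ta <- a$td_anterior
  if (!is.null(ta) && is.finite(ta) && ta > premature_wtol)
    return("premature-touchdown")
  NULL
}

#' Trace a branch of periodic gaits
#'
#' Pseudo-arclength predictor-corrector continuation of the one-dimensional
#' family of periodic solutions through a converged gait, at fixed model
#' parameters, in the full candidate space (apex state, event times, stride
#' time).  The step length adapts (halving on corrector failure, growing on
#' easy convergence); every accepted solution is classified and verified
#' against an event-detecting stride.  Termination reasons include a
#' degenerate verification (fall, premature touchdown, a change of contact
#' structure such as mid-flight grazing), the swing-amplitude cap of 1.7
#' rad, the forward-speed cap, folding back onto the start (closed loop),
#' corrector failure, or the point budget.
#'
#' @param start a converged `slip_gait` (with realized event times).
#' @param p model parameters (default: from `start`).
#' @param direction `"+"`, `"-"` (initial tangent along increasing /
#'   decreasing total energy) or `"both"`.
#' @param h0,h_min,h_max arclength step control.
#' @param max_points per-direction solution budget.
#' @param speed_cap terminate when `|xdot0|` exceeds this \[sqrt(g*lo)\].
#' @param amp_cap terminate when the swing amplitude exceeds this \[rad\]
#'   (default unbounded; the amplitude is recorded per solution).
#' @param premature_wtol anterior angular-rate threshold at a solved
#'   touchdown above which a solution is degenerate (terminates the branch).
#' @param rtol,atol integration tolerances.
#' @param ... passed to the verification [simulate_stride()].
#' @return An object of class `slip_branch`: candidates `X` (one row per
#'   solution, ordered along the branch), reduced states `S`, a per-solution
#'   data frame `info` (energy, apex speed, timings, label, metrics), and
#'   termination reasons.
#' @export
continue_branch <- function(start, p = NULL, direction = c("both", "+", "-"),
                            h0 = 0.02, h_min = 1e-7, h_max = 0.4,
                            max_points = 600, speed_cap = 30,
                            amp_cap = Inf, premature_wtol = 0.05,
                            rtol = 1e-9, atol = 1e-11, ...) {
  direction <- match.arg(direction)
  if (is.null(p)) p <- start$params
  stopifnot(inherits(start, "slip_gait"), isTRUE(start$converged))
  Ffun <- branch_residual_bvp(p, rtol = rtol, atol = atol)
  u0 <- as_candidate(start)
  stop_fun <- function(u, a)
    candidate_stop_reason(u, a, speed_cap, amp_cap, premature_wtol)
  orient_E <- function(sgn) function(tau, u) {
    dE <- tau[2] * u[2] + tau[1]  # d(apex energy) along tau (m=g=1 units)
    s <- sign(dE) * sgn
    if (s == 0) sgn else s
  }
  runs <- list()
  if (direction %in% c("both", "+"))
    runs$pos <- continue_curve(Ffun, u0, h0 = h0, h_min = h_min,
                               h_max = h_max, max_points = max_points,
                               orient = orient_E(+1), stop_fun = stop_fun)
  if (direction %in% c("both", "-"))
    runs$neg <- continue_curve(Ffun, u0, h0 = h0, h_min = h_min,
                               h_max = h_max, max_points = max_points,
                               orient = orient_E(-1), stop_fun = stop_fun)
  assemble_branch(runs, p)
}

expand_sym <- function(u) c(u[1:2], u[3], u[4], u[3], u[4])

assemble_branch <- function(runs, p) {
  Us <- list()
  term <- list(start = NA_character_, end = NA_character_)
  closed <- FALSE
  if (!is.null(runs$neg) && !is.null(runs$neg$U)) {
    nn <- nrow(runs$neg$U)
    Us$neg <- runs$neg$U[rev(seq_len(nn)), , drop = FALSE]
    term$start <- runs$neg$termination
    closed <- closed || runs$neg$closed
  }
  if (!is.null(runs$pos) && !is.null(runs$pos$U)) {
    keep <- if (length(Us)) -1L else TRUE  # drop duplicated seed point
    Us$pos <- runs$pos$U[keep, , drop = FALSE]
    term$end <- runs$pos$termination
    closed <- closed || runs$pos$closed
  }
  if (!length(Us) || !nrow(do.call(rbind, Us)))
    return(structure(list(X = NULL, S = NULL, info = NULL, params = p,
                          termination = term, closed = FALSE, n = 0L),
                     class = "slip_branch"))
  X <- do.call(rbind, Us)
  colnames(X) <- candidate_names
  S <- X[, 1:6, drop = FALSE]
  info <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    tt <- list(tltd = X[i, 7], tllo = X[i, 8], trtd = X[i, 9],
               trlo = X[i, 10], T = X[i, 11])
    lab <- classify_gait(tt)
    # stride length from the candidate: x(T) advance
    data.frame(E = apex_energy(X[i, ], p), y0 = X[i, 1], xdot0 = X[i, 2],
               T = X[i, 11], tltd = tt$tltd, tllo = tt$tllo,
               trtd = tt$trtd, trlo = tt$trlo, label = lab,
               stringsAsFactors = FALSE)
  }))
  structure(list(X = X, S = S, info = info, params = p, termination = term,
                 closed = closed, n = nrow(X)), class = "slip_branch")
}

#' @export
print.slip_branch <- function(x, ...) {
  cat(sprintf("slip_branch: %d solutions%s\n", x$n,
              if (x$closed) " (closed loop)" else ""))
  if (x$n) {
    cat(sprintf("  apex speed range [%.4g, %.4g], energy [%.4g, %.4g]\n",
                min(x$info$xdot0), max(x$info$xdot0), min(x$info$E),
                max(x$info$E)))
    tb <- table(x$info$label)
    cat("  labels:", paste(names(tb), tb, collapse = ", "), "\n")
    cat(sprintf("  termination: %s <- ... -> %s\n", x$termination$start,
                x$termination$end))
  }
  invisible(x)
}

#' @export
plot.slip_branch <- function(x, xvar = "xdot0", yvar = "y0", ...) {
  stopifnot(x$n > 0)
  cols <- c(walking = "purple", hopping = "red", skipping = "blue",
            symmetric_running = "orange", asymmetric_running = "darkgreen",
            degenerate = "grey")
  plot(x$info[[xvar]], x$info[[yvar]], col = cols[x$info$label], pch = 16,
       cex = 0.5, xlab = xvar, ylab = yvar, ...)
  invisible(x)
}

# extract the i-th solution of a branch as a slip_gait
branch_solution <- function(branch, i, ...) {
  build_gait_from_candidate(branch$X[i, ], branch$params, converged = TRUE,
                            residual_norm = NA_real_, ...)
}

#' Detect +1 Floquet-multiplier bifurcations along a branch
#'
#' At a leg-synchronized (hopping) stretch of a branch with
#' `phi_l == phi_r`, the monodromy block-diagonalizes into leg-symmetric and
#' leg-antisymmetric invariant subspaces; the trivial unit multiplier (the
#' branch/energy direction) lives in the symmetric block, so the
#' symmetry-breaking (hop-skip) test function is `det(M_a - I)` over the
#' 2x2 antisymmetric block `M_a`.  For general solutions the full spectrum
#' is scanned, the multiplier closest to +1 is discarded as the trivial one,
#' and sign changes of `(lambda - 1)` over the remaining real multipliers
#' are bracketed.  Bracketed crossings are refined by bisection in
#' arclength, re-solving the gait system at each trial point.
#'
#' @param branch a `slip_branch`.
#' @param p model parameters (default from branch).
#' @param refine_tol bisection tolerance on the critical multiplier.
#' @param stride_every test every k-th branch point.
#' @param ... passed to [simulate_stride()] for the monodromy strides.
#' @return list of transition points; each has the refined `slip_gait`
#'   (`$solution`), `$type = "floquet+1"`, the critical multiplier and the
#'   critical eigenvector in reduced coordinates (`$direction`).
#' @export
detect_bifurcation <- function(branch, p = NULL, refine_tol = 1e-3,
                               stride_every = 1L, ...) {
  if (is.null(p)) p <- branch$params
  stopifnot(inherits(branch, "slip_branch"), branch$n > 1)
  idx <- seq(1, branch$n, by = stride_every)
  if (idx[length(idx)] != branch$n) idx <- c(idx, branch$n)
  sym_case <- isTRUE(all.equal(p$phi_l, p$phi_r))
  testval <- function(X) {
    s <- X[1:6]
    synced <- abs(X[7] - X[9]) < 1e-6 && abs(X[8] - X[10]) < 1e-6
    sol_ref <- structure(list(s = s, params = p, X = X), class = "slip_gait")
    if (sym_case && synced) {
      Ma <- antisym_block(s, p, times_ref = X[7:11], ...)
      if (is.null(Ma)) return(NA_real_)
      det(Ma - diag(2))
    } else {
      ev <- tryCatch(floquet_multipliers(sol_ref, p, ...),
                     error = function(e) NULL)
      if (is.null(ev)) return(NA_real_)
      lam <- ev[order(abs(ev - 1))]
      lam <- lam[-1]                       # drop the trivial unit multiplier
      lam <- Re(lam[abs(Im(lam)) < 1e-6])  # real multipliers only
      if (!length(lam)) return(1)
      lam[which.min(abs(lam - 1))] - 1
    }
  }
  Ffun <- branch_residual_bvp(p)
  g <- vapply(idx, function(i) testval(branch$X[i, ]), numeric(1))
  out <- list()
  for (k in seq_len(length(idx) - 1)) {
    g1 <- g[k]; g2 <- g[k + 1]
    if (!is.finite(g1) || !is.finite(g2) || g1 * g2 > 0) next
    ua <- branch$X[idx[k], ]; ub <- branch$X[idx[k + 1], ]
    for (it in 1:40) {
      um <- (ua + ub) / 2
      tau <- (ub - ua); tau <- tau / sqrt(sum(tau^2))
      G <- function(v) {
        r <- Ffun(v)
        out2 <- c(r, sum(tau * (v - um)))
        attributes(out2) <- attributes(r)[c("ok", "status")]
        out2
      }
      cs <- gn_solve(G, um, tol = default_gn_tol, maxit = 12)
      if (!cs$converged) break
      um <- cs$u
      gm <- testval(um)
      if (!is.finite(gm)) break
      if (abs(gm) < refine_tol || sqrt(sum((ub - ua)^2)) < 1e-10) {
        ua <- ub <- um
        break
      }
      if (gm * g1 > 0) { ua <- um; g1 <- gm } else { ub <- um; g2 <- gm }
    }
    X_ref <- (ua + ub) / 2
    sol <- build_gait_from_candidate(X_ref, p, converged = TRUE,
                                     residual_norm = NA_real_, ...)
    s_ref <- X_ref[1:6]
    synced <- abs(X_ref[7] - X_ref[9]) < 1e-6
    if (sym_case && synced) {
      Ma <- antisym_block(s_ref, p, times_ref = X_ref[7:11], ...)
      crit <- if (is.null(Ma)) list(m = NA_real_, v = rep(NA_real_, 6))
      else {
        ea <- eigen(Ma)
        jc <- which.min(abs(ea$values - 1))
        list(m = ea$values[jc], v = antisym_embed(Re(ea$vectors[, jc])))
      }
    } else {
      ev <- tryCatch(floquet_multipliers(
        structure(list(s = s_ref, params = p, X = X_ref),
                  class = "slip_gait"), p, ...), error = function(e) NULL)
      crit <- if (is.null(ev)) list(m = NA_real_, v = rep(NA_real_, 6))
      else {
        ord <- order(abs(ev - 1))
        list(m = ev[ord[2]], v = Re(attr(ev, "vectors")[, ord[2]]))
      }
    }
    out[[length(out) + 1]] <- list(solution = sol, type = "floquet+1",
                                   multiplier = crit$m, direction = crit$v)
  }
  out
}

#' Switch to the bifurcating branch at a +1 multiplier crossing
#'
#' Seeds a gait search from the bifurcation fixed point displaced along the
#' critical eigenvector (both signs, growing displacement), holding the
#' displacement amplitude fixed during the solve so the corrector cannot
#' fall back onto the old branch.  Succeeds when a converged solution with a
#' different gait label is found.
#'
#' @param tp a transition point from [detect_bifurcation()].
#' @param p model parameters.
#' @param delta0 initial displacement along the eigenvector.
#' @param delta_max displacement cap.
#' @param ... passed to verification.
#' @return a converged `slip_gait` on the new branch, or `NULL`.
#' @export
branch_switch <- function(tp, p = NULL, delta0 = 5e-3, delta_max = 0.2, ...) {
  if (is.null(p)) p <- tp$solution$params
  X0 <- as_candidate(tp$solution)
  v <- tp$direction / sqrt(sum(tp$direction^2))
  old_label <- tp$solution$label
  Ffun <- branch_residual_bvp(p)
  delta <- delta0
  while (delta <= delta_max) {
    for (sg in c(1, -1)) {
      seed <- X0
      seed[1:6] <- seed[1:6] + sg * delta * v
      G <- function(u) {
        r <- Ffun(u)
        out <- c(r, sum(v * (u[1:6] - X0[1:6])) - sg * delta)
        attributes(out) <- attributes(r)[c("ok", "status")]
        out
      }
      cs <- gn_solve(G, seed, tol = default_gn_tol, maxit = 15)
      if (cs$converged) {
        sol <- build_gait_from_candidate(cs$u, p, converged = TRUE,
                                         residual_norm = cs$norm, ...)
        if (sol$label != old_label && sol$label != "degenerate") return(sol)
      }
    }
    delta <- delta * 3
  }
  NULL
}

#' Locate a timing degeneracy (smooth gait transition) on a branch
#'
#' Walking turns into symmetric running, and skipping into asymmetric
#' running, not at a multiplier crossing but where two contact events become
#' simultaneous: one leg's touchdown coincides with the other leg's liftoff.
#' Because the event times are explicit unknowns of the gait system, the
#' degeneracy is a regular bordered root problem: periodicity plus a zero
#' timing gap.  It is solved directly, seeded from the branch point where
#' the gap is smallest (or brackets a sign change).
#'
#' @param branch a `slip_branch` (or a single converged `slip_gait` used as
#'   the seed).
#' @param p model parameters.
#' @param gap `"l_td_r_lo"` (left touchdown vs right liftoff, the
#'   left-advanced convention) or `"r_td_l_lo"`.
#' @param tol gap tolerance \[sqrt(lo/g)\].
#' @param ... passed to verification.
#' @return the refined transition `slip_gait` with attributes `gap` and
#'   `type = "timing-degeneracy"`, or `NULL` when no crossing is found.
#' @export
locate_timing_degeneracy <- function(branch, p = NULL,
                                     gap = c("l_td_r_lo", "r_td_l_lo"),
                                     tol = 1e-8, ...) {
  gap <- match.arg(gap)
  gidx <- if (gap == "l_td_r_lo") c(7L, 10L) else c(9L, 8L)
  if (inherits(branch, "slip_gait")) {
    if (is.null(p)) p <- branch$params
    seeds <- list(as_candidate(branch))
  } else {
    if (is.null(p)) p <- branch$params
    gv <- branch$X[, gidx[1]] - branch$X[, gidx[2]]
    cross <- which(diff(sign(gv)) != 0)
    seeds <- if (length(cross))
      lapply(cross, function(i) (branch$X[i, ] + branch$X[i + 1, ]) / 2)
    else list(branch$X[which.min(abs(gv)), ])
  }
  Ffun <- branch_residual_bvp(p)
  for (seed in seeds) {
    G <- function(u) {
      r <- Ffun(u)
      out <- c(r, u[gidx[1]] - u[gidx[2]])
      attributes(out) <- attributes(r)[c("ok", "status")]
      out
    }
    cs <- gn_solve(G, as.numeric(seed), tol = default_gn_tol, maxit = 30)
    if (!cs$converged) next
    gval <- cs$u[gidx[1]] - cs$u[gidx[2]]
    if (!is.finite(gval) || abs(gval) > tol) next
    sol <- build_gait_from_candidate(cs$u, p, converged = TRUE,
                                     residual_norm = cs$norm, ...)
    attr(sol, "gap") <- gval
    attr(sol, "type") <- "timing-degeneracy"
    return(sol)
  }
  NULL
}
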