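#' Find a periodic gait by shooting
#'
#' Solves the apex-return periodicity system `P(s) = s` (see
#' [periodicity_residual()]) with damped Gauss-Newton least squares.  The
#' model is conservative, so for fixed parameters the periodic solutions form
#' one-dimensional families; the remaining degree of freedom is closed by an
#' `anchor` (fixing total energy, apex forward speed, apex height, or stride
#' time), or left open (`"none"`), in which case the solver projects onto the
#' nearest point of the solution manifold (minimal-norm Gauss-Newton) - the
#' mode used internally by parameter tracking.
#'
#' @param seed reduced apex state `(y0, xdot0, alpha_l0, alphadot_l0,
#'   alpha_r0, alphadot_r0)`, or a `slip_gait` to re-solve.
#' @param p model parameters.
#' @param anchor one of `"energy"`, `"speed"`, `"height"`, `"stride_time"`,
#'   `"none"`.
#' @param value anchor target value (ignored for `"none"`).
#' @param symmetric solve within the leg-synchronized subspace
#'   (`alpha_l = alpha_r`), the natural representation of hopping.
#' @param canonical canonicalize left-leg-advanced ordering (legs swapped if
#'   needed) when `phi_l == phi_r`.
#' @param tol convergence tolerance on the residual 2-norm.
#' @param maxit maximum Gauss-Newton iterations.
#' @param ... passed to [simulate_stride()] (e.g. `rtol`).
#' @return An object of class `slip_gait` (a periodic solution) with the
#'   reduced apex state, event timings, energy, gait label, stride metrics
#'   and residual norm; `$converged` is `FALSE` on failure.
#' @examples
#' p <- slip_params()
#' hop <- find_gait(c(1.2, 0, 0, 0, 0, 0), p, anchor = "energy", value = 1.2)
#' hop$label
#' @export
find_gait <- function(seed, p = slip_params(),
                      anchor = c("energy", "speed", "height", "stride_time",
                                 "none"),
                      value = NULL, symmetric = FALSE, canonical = TRUE,
                      tol = default_gn_tol, maxit = 40, ...) {
  anchor <- match.arg(anchor)
  p <- as_slip_params(p)
  if (inherits(seed, "slip_gait")) seed <- seed$s
  seed <- as.numeric(seed)
  if (anchor != "none" && is.null(value))
    stop("anchor value required for anchor != 'none'")
  expand <- function(u) if (symmetric) c(u[1:2], u[3], u[4], u[3], u[4]) else u
  u0 <- if (symmetric) seed[1:4] else seed

  Fres <- function(u) {
    s <- expand(u)
    r <- periodicity_residual(s, p, ...)
    rr <- if (symmetric) r[1:4] else r
    extra <- switch(anchor,
      energy = apex_energy(s, p) - value,
      speed = s[2] - value,
      height = s[1] - value,
      stride_time = (attr(r, "T") %||% NA_real_) - value,
      none = numeric(0))
    out <- c(rr, extra)
    attributes(out) <- attributes(r)[c("ok", "status", "times", "T",
                                       "stride_length", "energy")]
    if (anchor == "stride_time" && !is.finite(extra)) attr(out, "ok") <- FALSE
    out
  }
  sol <- gn_solve(Fres, u0, tol = tol, maxit = maxit)
  s <- expand(sol$u)
  new_slip_gait(s, p, converged = sol$converged, residual_norm = sol$norm,
                niter = sol$niter, solver_status = sol$status,
                canonical = canonical, ...)
}

# Build the slip_gait record from a converged (or attempted) reduced state.
new_slip_gait <- function(s, p, converged, residual_norm, niter = NA_integer_,
                          solver_status = "converged", canonical = TRUE, ...) {
  pm <- poincare_map(s, p, ...)
  times <- pm$times
  if (canonical && pm$ok && isTRUE(all.equal(p$phi_l, p$phi_r)) &&
      all(is.finite(unlist(times[c("tltd", "trtd")]))) &&
      times$trtd - times$tltd > 1e-9) {
    s <- swap_legs_s(s)
    pm <- poincare_map(s, p, ...)
    times <- pm$times
  }
  lab <- if (pm$ok) classify_gait(times) else "degenerate"
  met <- if (pm$ok)
    stride_metrics(times, pm$stride_length)
  else list(duty_factor = NA_real_, stride_time = NA_real_,
            stride_length = NA_real_, average_speed = NA_real_)
  structure(list(
    s = setNames(as.numeric(s), reduced_names), params = p, times = times,
    T = pm$T, label = lab, energy = if (pm$ok) apex_energy(s, p) else NA_real_,
    apex_speed = s[2], stride_length = met$stride_length,
    average_speed = met$average_speed, duty_factor = met$duty_factor,
    residual_norm = residual_norm, converged = isTRUE(converged),
    niter = niter, solver_status = solver_status,
    amp_max = if (!is.null(pm$stride)) pm$stride$amp_max else NA_real_,
    status = pm$status, floquet = NULL), class = "slip_gait")
}

#' @export
print.slip_gait <- function(x, ...) {
  cat(sprintf("slip_gait: %s%s\n", x$label,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  apex: y0 %.6g, xdot0 %.6g | E %.6g | residual %.2e\n",
              x$s[1], x$s[2], x$energy, x$residual_norm))
  tt <- x$times
  cat(sprintf("  times: l td/lo %.4g/%.4g, r td/lo %.4g/%.4g, T %.6g\n",
              tt$tltd, tt$tllo, tt$trtd, tt$trlo, tt$T))
  cat(sprintf("  duty %.3g, stride length %.4g, avg speed %.4g\n",
              x$duty_factor, x$stride_length, x$average_speed))
  invisible(x)
}

#' @export
summary.slip_gait <- function(object, ...) {
  print(object)
  if (!is.null(object$floquet)) {
    cat("  Floquet multiplier moduli:",
        paste(format(Mod(object$floquet), digits = 4), collapse = ", "), "\n")
  }
  invisible(object)
}

# ---- classification ------------------------------------------------------

# Merge per-leg stance intervals on the stride circle [0, T) and return the
# complementary aerial phases as a matrix (start, duration).
aerial_phases <- function(times, T) {
  ivs <- list()
  for (leg in c("l", "r")) {
    td <- times[[paste0("t", leg, "td")]]
    lo <- times[[paste0("t", leg, "lo")]]
    if (!is.finite(td) || !is.finite(lo)) next
    if (lo >= td) ivs <- c(ivs, list(c(td, lo)))
    else ivs <- c(ivs, list(c(0, lo), c(td, T)))
  }
  if (!length(ivs)) return(matrix(numeric(0), 0, 2))
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    k <- nrow(merged)
    if (m[i, 1] <= merged[k, 2] + 1e-12)
      merged[k, 2] <- max(merged[k, 2], m[i, 2])
    else merged <- rbind(merged, m[i, ])
  }
  gaps <- matrix(numeric(0), 0, 2)
  k <- nrow(merged)
  for (i in seq_len(k - 1))
    gaps <- rbind(gaps, c(merged[i, 2], merged[i + 1, 1] - merged[i, 2]))
  # cyclic wrap gap
  wrap <- (T - merged[k, 2]) + merged[1, 1]
  if (wrap > 1e-12) gaps <- rbind(gaps, c(merged[k, 2], wrap))
  colnames(gaps) <- c("start", "duration")
  gaps
}

#' Classify a periodic solution into a gait
#'
#' Labels a solution from its touchdown/liftoff pattern: `hopping`
#' (synchronized leg events), `walking` (no aerial phase), `skipping`
#' (overlapping but staggered stances, one aerial phase), and running with
#' two aerial phases per stride - `symmetric_running` when the two aerial
#' phases have equal duration (leg events offset by half a stride),
#' `asymmetric_running` when they differ.  Equalities are tested before
#' strict orderings, at tolerance `tol_t`.
#'
#' @param sol a `slip_gait`, or a list of event times with elements `tltd`,
#'   `tllo`, `trtd`, `trlo` and `T`.
#' @param tol_t timing tolerance \[sqrt(lo/g)\]; default `1e-3 * T`.
#' @return one of `"walking"`, `"hopping"`, `"skipping"`,
#'   `"symmetric_running"`, `"asymmetric_running"`, `"degenerate"`.
#' @examples
#' classify_gait(list(tltd = .3, tllo = .6, trtd = .3, trlo = .6, T = 1))
#' @export
classify_gait <- function(sol, tol_t = NULL) {
  times <- if (inherits(sol, "slip_gait")) sol$times else sol
  T <- times$T
  if (!is.finite(T) || T <= 0) return("degenerate")
  if (is.null(tol_t)) tol_t <- 1e-3 * T
  tt <- unlist(times[c("tltd", "tllo", "trtd", "trlo")])
  if (any(!is.finite(tt)) || any(tt < 0) || any(tt >= T)) return("degenerate")
  if (abs(times$tltd - times$trtd) <= tol_t &&
      abs(times$tllo - times$trlo) <= tol_t) return("hopping")
  aer <- aerial_phases(times, T)
  aer <- aer[aer[, 2] > tol_t, , drop = FALSE]
  n <- nrow(aer)
  if (n == 0) return("walking")
  if (n == 1) return("skipping")
  if (n == 2) {
    return(if (abs(aer[1, 2] - aer[2, 2]) <= tol_t) "symmetric_running"
           else "asymmetric_running")
  }
  "degenerate"
}

# duty factor, stride time/length, average speed from realized timings
stride_metrics <- function(times, stride_length) {
  T <- times$T
  st <- vapply(c("l", "r"), function(leg) {
    td <- times[[paste0("t", leg, "td")]]
    lo <- times[[paste0("t", leg, "lo")]]
    if (!is.finite(td) || !is.finite(lo)) return(NA_real_)
    if (lo >= td) lo - td else (T - td) + lo
  }, numeric(1))
  list(duty_factor = mean(st) / T, stride_time = T,
       stride_length = stride_length, average_speed = stride_length / T)
}

#' Stride metrics of a periodic solution
#'
#' Duty factor (mean per-leg stance fraction of the stride), stride time,
#' stride length and average forward speed (stride length over stride time).
#'
#' @param sol a `slip_gait`.
#' @return named list.
#' @export
gait_metrics <- function(sol) {
  stopifnot(inherits(sol, "slip_gait"))
  stride_metrics(sol$times, sol$stride_length)
}
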