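# Fitting periodic model gaits to kinematic stride recordings.
#
# The cost is the integrated squared deviation of positions and velocities
# between a periodic model solution and an observed stride (COM position
# and both leg angles, all channels weighted equally, trapezoidal
# quadrature on the empirical time grid).  The empirical stride duration
# anchors the model's stride time, and the remaining free parameters
# (typically omega, phi_l, phi_r) are adjusted by a derivative-free
# simplex search with the periodic solution re-solved (warm-started) at
# each candidate.

traj_channels <- c("x", "y", "alpha_l", "alpha_r")
traj_vel_channels <- c("xdot", "ydot", "alphadot_l", "alphadot_r")

check_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("t", traj_channels) %in% names(traj)))
  if (is.unsorted(traj$t, strictly = TRUE))
    stop("trajectory times must be strictly increasing")
  traj
}

# velocities: use recorded columns when present, otherwise central finite
# differences of the positions on the sample grid (and then the model is
# differenced the same way, so the comparison is consistent)
traj_velocities <- function(traj) {
  if (all(traj_vel_channels %in% names(traj)))
    return(list(v = as.matrix(traj[traj_vel_channels]), fd = FALSE))
  list(v = fd_velocities(as.matrix(traj[traj_channels]), traj$t), fd = TRUE)
}

fd_velocities <- function(Q, t) {
  n <- nrow(Q)
  V <- matrix(NA_real_, n, ncol(Q))
  if (n >= 3) {
    V[2:(n - 1), ] <- (Q[3:n, , drop = FALSE] -
                         Q[1:(n - 2), , drop = FALSE]) /
      (t[3:n] - t[1:(n - 2)])
  }
  V[1, ] <- (Q[2, ] - Q[1, ]) / (t[2] - t[1])
  V[n, ] <- (Q[n, ] - Q[n - 1, ]) / (t[n] - t[n - 1])
  colnames(V) <- traj_vel_channels
  V
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Trajectory-matching cost of a periodic solution
#'
#' Integrated squared deviation (positions plus velocities, all four
#' channels, trapezoidal quadrature on the empirical grid) between the
#' model stride and an observed stride.  The model is sampled at the
#' empirical times; horizontal position is aligned by shifting both
#' trajectories to start at `x = 0`, so the cost is invariant to the
#' recording's x-origin.  When the data carry no velocity columns, both
#' data and model velocities are central finite differences on the sample
#' grid.
#'
#' @param sol a converged `slip_gait`.
#' @param traj a kinematic trajectory data frame (columns `t, x, y,
#'   alpha_l, alpha_r`, optionally the four velocity columns), one stride
#'   starting at the flight apex.
#' @return the scalar cost, with per-channel squared-error attributes.
#' @export
trajectory_cost <- function(sol, traj) {
  traj <- check_trajectory(traj)
  tt <- traj$t - traj$t[1]
  T_data <- attr(traj, "stride_time") %||% (max(tt) + median(diff(tt)))
  mt <- tryCatch(gait_trajectory(sol, t_eval = pmin(tt, sol$T)),
                 error = function(e) NULL)
  if (is.null(mt) || nrow(mt) != length(tt)) return(1e6)
  Qd <- as.matrix(traj[traj_channels])
  Qd[, "x"] <- Qd[, "x"] - Qd[1, "x"]
  Qm <- as.matrix(mt[traj_channels])
  Qm[, "x"] <- Qm[, "x"] - Qm[1, "x"]
  vd <- traj_velocities(traj)
  Vm <- if (vd$fd) fd_velocities(Qm, tt) else as.matrix(mt[traj_vel_channels])
  per <- vapply(seq_len(4), function(j) {
    trapz(tt, (Qm[, j] - Qd[, j])^2) + trapz(tt, (Vm[, j] - vd$v[, j])^2)
  }, numeric(1))
  structure(sum(per), channels = setNames(per, traj_channels),
            T_data = T_data)
}

#' Coefficient of determination of a fitted channel
#'
#' `1 - SS_res / SS_tot` of one kinematic channel of the model stride
#' against the data (positions only, the convention of the validation
#' tables).
#'
#' @param sol a converged `slip_gait`.
#' @param traj kinematic trajectory data frame.
#' @param channel one of `"x"`, `"y"`, `"alpha_l"`, `"alpha_r"`.
#' @return scalar (`NA` with a warning for a zero-variance channel).
#' @export
r_squared <- function(sol, traj, channel = traj_channels) {
  channel <- match.arg(channel)
  traj <- check_trajectory(traj)
  tt <- traj$t - traj$t[1]
  mt <- gait_trajectory(sol, t_eval = pmin(tt, sol$T))
  yd <- traj[[channel]]
  ym <- mt[[channel]]
  if (channel == "x") {
    yd <- yd - yd[1]
    ym <- ym - ym[1]
  }
  ss_tot <- sum((yd - mean(yd))^2)
  if (ss_tot < 1e-14) {
    warning("zero-variance channel: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((ym - yd)^2) / ss_tot
}

#' Fit model parameters to an observed stride
#'
#' Minimizes [trajectory_cost()] over a subset of model parameters
#' (default: swing frequency and the two neutral leg swing angles; leg
#' stiffness is held at its nominal value unless freed).  For each
#' candidate parameter vector the periodic solution is re-solved by
#' [find_gait_bvp()], warm-started from the previous solution and anchored
#' at the empirical stride time, so the optimization searches the joint
#' space of parameters and periodic solutions.  The search is a
#' derivative-free Nelder-Mead simplex.
#'
#' @param traj kinematic trajectory data frame: columns `t, x, y, alpha_l,
#'   alpha_r` (optionally velocities), one stride starting at a flight
#'   apex.
#' @param init a converged `slip_gait` at the initial parameters (the
#'   convergence basin seed).
#' @param free names of free parameters among `"omega"`, `"phi_l"`,
#'   `"phi_r"`, `"k"`.
#' @param maxit simplex iteration budget.
#' @param ... passed to [find_gait_bvp()].
#' @return An object of class `slip_fit`: optimal parameters, the fitted
#'   periodic solution, the cost `C_opt`, per-channel R-squared, and the
#'   optimizer trace.
#' @export
fit_slip <- function(traj, init, free = c("omega", "phi_l", "phi_r"),
                     maxit = 300, ...) {
  traj <- check_trajectory(traj)
  stopifnot(inherits(init, "slip_gait"), isTRUE(init$converged))
  free <- match.arg(free, c("omega", "phi_l", "phi_r", "k"), several.ok = TRUE)
  p0 <- init$params
  tt <- traj$t - traj$t[1]
  T_data <- attr(traj, "stride_time") %||% (max(tt) + median(diff(tt)))
  env <- new.env()
  env$X <- as_candidate(init)
  env$trace <- numeric(0)
  make_p <- function(th) {
    pl <- list(k = p0$k, omega = p0$omega, phi_l = p0$phi_l,
               phi_r = p0$phi_r, m = p0$m, lo = p0$lo, g = p0$g)
    pl[free] <- as.list(th)
    do.call(slip_params, pl)
  }
  obj <- function(th) {
    p <- tryCatch(make_p(th), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    g <- find_gait_bvp(env$X, p, anchor = "stride_time", value = T_data,
                       ...)
    if (!g$converged) return(1e6)
    env$X <- g$X
    cst <- as.numeric(trajectory_cost(g, traj))
    env$trace <- c(env$trace, cst)
    cst
  }
  th0 <- unlist(p0[free])
  opt <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  p_opt <- make_p(opt$par)
  sol <- find_gait_bvp(env$X, p_opt, anchor = "stride_time",
                       value = T_data, ...)
  r2 <- vapply(traj_channels, function(ch)
    suppressWarnings(r_squared(sol, traj, ch)), numeric(1))
  structure(list(par = setNames(opt$par, free), params = p_opt,
                 solution = sol, cost = opt$value, r_squared = r2,
                 traj = traj, stride_time = T_data,
                 convergence = opt$convergence, trace = env$trace,
                 counts = opt$counts), class = "slip_fit")
}

#' @export
print.slip_fit <- function(x, ...) {
  cat("slip_fit: periodic gait fitted to a recorded stride\n")
  cat("  parameters:", paste(sprintf("%s = %.4g", names(x$par), x$par),
                             collapse = ", "), "\n")
  cat(sprintf("  cost C_opt = %.6g, gait = %s\n", x$cost,
              x$solution$label))
  cat("  R-squared:", paste(sprintf("%s %.3f", names(x$r_squared),
                                    x$r_squared), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.slip_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  optimizer: %d cost evaluations, convergence code %d\n",
              object$counts[1], object$convergence))
  print(object$solution)
  invisible(object)
}

#' @export
coef.slip_fit <- function(object, ...) object$par

#' @export
predict.slip_fit <- function(object, t = NULL, ...) {
  tt <- if (is.null(t)) object$traj$t - object$traj$t[1] else t
  gait_trajectory(object$solution, t_eval = pmin(tt, object$solution$T))
}

#' @export
residuals.slip_fit <- function(object, ...) {
  traj <- object$traj
  tt <- traj$t - traj$t[1]
  mt <- predict(object)
  out <- as.matrix(traj[traj_channels]) - as.matrix(mt[traj_channels])
  out[, "x"] <- out[, "x"] - out[1, "x"]
  out
}

#' @export
plot.slip_fit <- function(x, which = c("com", "angles"), ...) {
  which <- match.arg(which)
  traj <- x$traj
  tt <- traj$t - traj$t[1]
  mt <- predict(x)
  if (which == "com") {
    plot(tt, traj$y, pch = 1, cex = 0.6, xlab = "t [sqrt(lo/g)]",
         ylab = "y [lo]", main = "COM height: data (points) vs fit (line)",
         ...)
    lines(tt, mt$y, col = "firebrick", lwd = 2)
  } else {
    matplot(tt, cbind(traj$alpha_l, traj$alpha_r), pch = 1, cex = 0.6,
            col = c("navy", "skyblue"), xlab = "t [sqrt(lo/g)]",
            ylab = "alpha [rad]", main = "leg angles: data vs fit", ...)
    matplot(tt, cbind(mt$alpha_l, mt$alpha_r), type = "l", lty = 1,
            col = c("navy", "skyblue"), add = TRUE, lwd = 2)
    legend("topright", c("left", "right"), col = c("navy", "skyblue"),
           lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
simulate.slip_fit <- function(object, nsim = 1, seed = NULL, sigma = 0.005,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    generate_fixture(object$solution,
                     frame_rate = attr(object$traj, "frame_rate") %||% 39.1,
                     sigma = sigma, seed = sample.int(2^31 - 2, 1)))
}
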