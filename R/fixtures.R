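# Synthetic-kinematics generation.
#
# Real input data for the fitting module are markerless pose tracks of
# hopping rodents filmed at 500 frames per second.  The generator emulates
# them: a periodic model stride is sampled at a fixed frame rate and
# corrupted with independent Gaussian noise per channel.  The default frame
# rate converts 500 fps to dimensionless time using a representative
# jerboa scale (effective leg length 0.06 m, g = 9.81 m/s^2, so one time
# unit is sqrt(0.06/9.81) = 0.078 s and one frame is 0.0256 time units,
# about 39.1 frames per time unit).

default_frame_rate <- function() 500 * sqrt(0.06 / 9.81)

#' Generate a synthetic kinematic stride
#'
#' Samples one stride of a periodic solution at a fixed frame rate and adds
#' independent Gaussian noise to every position channel.  Velocity columns
#' are central finite differences of the noisy positions (so that fitting
#' compares model and data velocities computed by the same scheme), unless
#' `velocities = "exact"` requests the noiseless model velocities.
#'
#' @param sol a converged `slip_gait`.
#' @param frame_rate frames per unit time \[1/sqrt(lo/g)\]; the default is
#'   500 fps at a representative jerboa scale.
#' @param sigma position noise standard deviation \[lo\] (angles \[rad\]).
#' @param seed RNG seed recorded in the output (reproducible).
#' @param velocities `"fd"` (finite differences of noisy positions, the
#'   default) or `"exact"`.
#' @return a kinematic trajectory data frame (columns `t, x, y, alpha_l,
#'   alpha_r, xdot, ydot, alphadot_l, alphadot_r`) with attributes
#'   `frame_rate`, `sigma`, `seed`, `stride_time`, `params` and
#'   `provenance = "synthetic"`.
#' @examples
#' p <- slip_params()
#' hop <- find_gait(c(1.2, 0, 0, 0, 0, 0), p, anchor = "energy", value = 1.2)
#' traj <- generate_fixture(hop, sigma = 0, seed = 1)
#' @export
generate_fixture <- function(sol, frame_rate = default_frame_rate(),
                             sigma = 0.005, seed = 1,
                             velocities = c("fd", "exact")) {
  velocities <- match.arg(velocities)
  stopifnot(inherits(sol, "slip_gait"), isTRUE(sol$converged),
            frame_rate > 0, sigma >= 0)
  T <- sol$T
  tt <- seq(0, T, by = 1 / frame_rate)
  mt <- gait_trajectory(sol, t_eval = tt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Q <- as.matrix(mt[traj_channels])
  Qn <- Q + matrix(rnorm(length(Q), sd = sigma), nrow(Q), ncol(Q))
  out <- data.frame(t = mt$t, Qn)
  names(out) <- c("t", traj_channels)
  V <- if (velocities == "fd") fd_velocities(Qn, mt$t)
  else as.matrix(mt[traj_vel_channels])
  out <- cbind(out, as.data.frame(V))
  names(out) <- c("t", traj_channels, traj_vel_channels)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  attr(out, "stride_time") <- unname(T)
  attr(out, "params") <- sol$params
  attr(out, "provenance") <- "synthetic"
  out
}

#' A jerboa-like skipping gait and fixture
#'
#' Builds the skipping solution used as the package's stand-in for a real
#' recorded trial: swing frequency 6.49, neutral angles (0.02, 0.17) rad,
#' apex forward speed 2.86 (the parameter row of a published skipping
#' trial), obtained by tracking the nominal skipping branch through
#' parameter space.  When the requested speed is beyond the traced branch
#' segment at those (strongly uncoupled) angles, the nearest feasible
#' branch point is returned instead - the published per-trial states are
#' not exactly recomputable and this gait is a synthetic stand-in.
#'
#' @param p_nominal nominal parameters used for the bootstrap.
#' @param omega,phi_l,phi_r,speed target configuration.
#' @param nominal optionally a precomputed [nominal_gait_structure()].
#' @return a converged `slip_gait` (label `"skipping"`).
#' @export
jerboa_skipping_gait <- function(p_nominal = slip_params(), omega = 6.49,
                                 phi_l = 0.02, phi_r = 0.17, speed = 2.86,
                                 nominal = NULL) {
  if (is.null(nominal))
    nominal <- nominal_gait_structure(p_nominal, with_running = FALSE)
  br <- nominal$skip_ar
  if (is.null(br) || br$n == 0) stop("no skipping branch available")
  # start near a skip/AR transition: these deform most robustly under
  # uncoupling of the neutral angles
  isk <- which(br$info$label == "skipping")
  if (!length(isk)) stop("no skipping solution in the nominal structure")
  gapL <- abs(br$X[isk, 7] - br$X[isk, 10])
  gapR <- abs(br$X[isk, 9] - br$X[isk, 8])
  starts <- unique(c(isk[which.min(gapL)], isk[which.min(gapR)],
                     isk[order(pmin(gapL, gapR))[seq_len(min(6,
                                                             length(isk)))]]))
  p_t <- slip_params(k = p_nominal$k, omega = omega, phi_l = phi_l,
                     phi_r = phi_r)
  frontier <- lapply(starts, function(i0)
    build_gait_from_candidate(br$X[i0, ], p_nominal, converged = TRUE,
                              residual_norm = NA_real_))
  # two-leg parameter path: first move the coupled structure to
  # (omega, phi_r, phi_r) - the symmetric skipping family persists across
  # moderate coupled angles - then lower phi_l alone to its target
  p_mid <- slip_params(k = p_nominal$k, omega = omega, phi_l = phi_r,
                       phi_r = phi_r)
  tr <- NULL
  for (g0 in frontier) {
    t1 <- track_gait(g0, p_mid, step = 0.1)
    if (!t1$reached) next
    t2 <- track_gait(t1$sol, p_t, step = 0.1)
    if (t2$reached) {
      tr <- t2
      break
    }
  }
  if (is.null(tr))
    stop("could not track skipping to the target parameters")
  # trace the branch at the target parameters and land on the target speed
  br2 <- continue_branch(tr$sol, p_t, direction = "both",
                         h0 = 0.05, h_max = 0.4, max_points = 500,
                         speed_cap = max(2 * speed, 8))
  i <- which.min(abs(br2$info$xdot0 - speed))
  g <- build_gait_from_candidate(br2$X[i, ], p_t, converged = TRUE,
                                 residual_norm = NA_real_)
  g2 <- find_gait_bvp(g, p_t, anchor = "speed", value = speed)
  if (g2$converged && isTRUE(g2$admissible)) g2 else g
}
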