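#' Model parameters for the bipedal SLIP model with passive swing legs
#'
#' Builds the dimensionless parameter vector of the template model: a point
#' mass `m` on two massless linear-spring legs of rest length `lo` and
#' stiffness `k`, with each swing leg driven by a passive torsional spring of
#' oscillation frequency `omega` toward its neutral leg swing angle (NLSA)
#' `phi_l` / `phi_r`.  All quantities are normalized by body mass, rest leg
#' length and gravity, so `m = lo = g = 1` in normal use; `k` is in units of
#' `m*g/lo`, `omega` in `sqrt(g/lo)` and angles in radians (measured from the
#' downward vertical through the hip, counterclockwise positive, forward
#' motion along +x).
#'
#' @param k leg spring stiffness \[m*g/lo\]. Default 20, the value used for
#'   the published jerboa gait-structure analyses.
#' @param omega swing-leg oscillation frequency \[sqrt(g/lo)\]. Default 6.5.
#' @param phi_l,phi_r neutral leg swing angles \[rad\].
#' @param m,lo,g body mass, rest leg length, gravity (normalized, default 1).
#' @return An object of class `slip_params`.
#' @examples
#' p <- slip_params()
#' p
#' @export
slip_params <- function(k = 20, omega = 6.5, phi_l = 0, phi_r = 0,
                        m = 1, lo = 1, g = 1) {
  stopifnot(is.numeric(k), is.numeric(omega), is.numeric(phi_l),
            is.numeric(phi_r), length(k) == 1, length(omega) == 1,
            length(phi_l) == 1, length(phi_r) == 1)
  if (m <= 0 || lo <= 0 || g <= 0 || k <= 0 || omega <= 0)
    stop("m, lo, g, k and omega must all be positive")
  structure(list(m = m, lo = lo, g = g, k = k, omega = omega,
                 phi_l = phi_l, phi_r = phi_r),
            class = "slip_params")
}

#' @export
print.slip_params <- function(x, ...) {
  cat("Bipedal SLIP parameters (dimensionless, m = lo = g normalization):\n")
  cat(sprintf("  k     = %g [m*g/lo]\n", x$k))
  cat(sprintf("  omega = %g [sqrt(g/lo)]\n", x$omega))
  cat(sprintf("  phi_l = %g, phi_r = %g [rad]\n", x$phi_l, x$phi_r))
  if (x$m != 1 || x$lo != 1 || x$g != 1)
    cat(sprintf("  m = %g, lo = %g, g = %g\n", x$m, x$lo, x$g))
  invisible(x)
}

# internal: parameter vector for the C++ kernel
par_vec <- function(p) {
  c(p$m, p$lo, p$g, p$k, p$omega, p$phi_l, p$phi_r)
}

as_slip_params <- function(p) {
  if (inherits(p, "slip_params")) return(p)
  if (is.list(p)) return(do.call(slip_params, p))
  stop("cannot interpret 'p' as slip_params")
}
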