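#' Monodromy matrix of a periodic solution
#'
#' Central finite-difference Jacobian of the apex return map at the fixed
#' point, in the six reduced section coordinates.  Its eigenvalues are the
#' Floquet multipliers of the gait; for this conservative model one
#' multiplier equals +1 up to numerical tolerance (the direction along the
#' solution branch / energy family), and a further multiplier crossing +1
#' marks a bifurcation to another gait.  The touchdown velocity reset makes
#' the return map non-invertible, so zero multipliers also occur
#' structurally.
#'
#' When the solution carries its event times (`$X`, the usual case) the map
#' is evaluated in the boundary-value form - contact times slaved to the
#' state by Newton - which remains defined for solutions whose swing foot
#' passes below ground between events; otherwise the event-detecting
#' simulator is differenced.
#'
#' @param sol a converged `slip_gait` (or a reduced state on the manifold).
#' @param p model parameters (taken from `sol` if omitted).
#' @param h finite-difference step.
#' @param ... passed to the underlying map evaluation.
#' @return a 6x6 matrix.
#' @export
monodromy <- function(sol, p = NULL, h = 1e-6, ...) {
  if (inherits(sol, "slip_gait")) {
    s <- sol$s
    if (is.null(p)) p <- sol$params
    times_ref <- if (!is.null(sol$X)) sol$X[7:11] else NULL
  } else {
    s <- as.numeric(sol)
    times_ref <- NULL
    if (is.null(p)) stop("p required")
  }
  map <- if (!is.null(times_ref)) {
    function(sv) {
      pm <- poincare_map_bvp(sv, times_ref, p, ...)
      if (is.null(pm)) NULL else pm$s
    }
  } else {
    function(sv) {
      pm <- poincare_map(sv, p, ...)
      if (pm$ok) pm$s else NULL
    }
  }
  M <- matrix(NA_real_, 6, 6)
  for (j in 1:6) {
    hj <- h * max(1, abs(s[j]))
    for (try in 1:3) {
      pp <- map(s + hj * (1:6 == j))
      pmm <- map(s - hj * (1:6 == j))
      if (!is.null(pp) && !is.null(pmm)) {
        M[, j] <- (pp - pmm) / (2 * hj)
        break
      }
      hj <- hj / 10
    }
    if (any(!is.finite(M[, j])))
      stop("monodromy: stride failure under perturbation of coordinate ", j)
  }
  M
}

#' Floquet multipliers of a periodic solution
#'
#' @inheritParams monodromy
#' @return complex eigenvalues of the linearized return map (decreasing
#'   modulus), with the eigenvectors as attribute `vectors`.
#' @export
floquet_multipliers <- function(sol, p = NULL, h = 1e-6, ...) {
  M <- monodromy(sol, p, h = h, ...)
  e <- eigen(M)
  ord <- order(-Mod(e$values))
  structure(e$values[ord], vectors = e$vectors[, ord, drop = FALSE],
            monodromy = M)
}

# Antisymmetric (leg-desynchronizing) block of the monodromy at a
# leg-synchronized solution.  For phi_l = phi_r the dynamics commute with
# the leg-swap involution, so at a hopping fixed point the monodromy block-
# diagonalizes into symmetric and antisymmetric invariant subspaces; the
# 2-dimensional antisymmetric block can be probed with two perturbations
# only, and its eigenvalue crossing +1 is the symmetry-breaking (hop-skip)
# bifurcation test function.
antisym_block <- function(s, p, h = 1e-6, times_ref = NULL, ...) {
  q1 <- c(0, 0, 1, 0, -1, 0) / sqrt(2)
  q2 <- c(0, 0, 0, 1, 0, -1) / sqrt(2)
  Q <- cbind(q1, q2)
  map <- if (!is.null(times_ref)) {
    function(sv) {
      pm <- poincare_map_bvp(sv, times_ref, p, ...)
      if (is.null(pm)) NULL else pm$s
    }
  } else {
    function(sv) {
      pm <- poincare_map(sv, p, ...)
      if (pm$ok) pm$s else NULL
    }
  }
  MQ <- matrix(NA_real_, 6, 2)
  for (j in 1:2) {
    pp <- map(s + h * Q[, j])
    pmm <- map(s - h * Q[, j])
    if (is.null(pp) || is.null(pmm)) return(NULL)
    MQ[, j] <- (pp - pmm) / (2 * h)
  }
  crossprod(Q, MQ)
}

# embed an antisymmetric-block vector back into the full reduced space
antisym_embed <- function(v2) {
  q1 <- c(0, 0, 1, 0, -1, 0) / sqrt(2)
  q2 <- c(0, 0, 0, 1, 0, -1) / sqrt(2)
  v2[1] * q1 + v2[2] * q2
}
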