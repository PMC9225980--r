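#' Eigenvalues of a 2x2 Jacobian
#'
#' Closed-form roots of the characteristic polynomial
#' \eqn{\lambda^2 - tr(J)\lambda + det(J)}; no iterative solver is
#' involved.  The dominant real part drives the recovery rate after a small
#' perturbation (engineering resilience is its negative).
#'
#' @param J 2x2 numeric matrix (see \code{\link{cr_jacobian}}).
#' @return object of class \code{cr_eigen}: complex \code{lambda1},
#'   \code{lambda2} (conjugate pair when the discriminant is negative,
#'   \code{lambda1} carrying the non-negative imaginary part),
#'   \code{dominant_real}, plus \code{trace}, \code{det} and
#'   \code{discriminant}.
#' @export
eigen_pair <- function(J) {
  if (!is.matrix(J) || any(dim(J) != 2L) || any(!is.finite(J)))
    stop("J must be a finite 2x2 matrix")
  tr <- J[1L, 1L] + J[2L, 2L]
  dt <- J[1L, 1L] * J[2L, 2L] - J[1L, 2L] * J[2L, 1L]
  disc <- tr^2 - 4 * dt
  if (disc >= 0) {
    s <- sqrt(disc)
    l1 <- complex(real = (tr + s) / 2)
    l2 <- complex(real = (tr - s) / 2)
  } else {
    s <- sqrt(-disc)
    l1 <- complex(real = tr / 2, imaginary = s / 2)
    l2 <- Conj(l1)
  }
  structure(list(lambda1 = l1, lambda2 = l2,
                 dominant_real = max(Re(l1), Re(l2)),
                 trace = tr, det = dt, discriminant = disc),
            class = "cr_eigen")
}

#' @export
print.cr_eigen <- function(x, ...) {
  cat(sprintf("<cr_eigen> lambda = %s, %s  (dominant Re = %.6g)\n",
              format(x$lambda1, digits = 6), format(x$lambda2, digits = 6),
              x$dominant_real))
  invisible(x)
}

#' Classify the local dynamical regime at an equilibrium
#'
#' Trace/determinant/discriminant classification in the style of the
#' standard planar-systems taxonomy: saddle (real eigenvalues of opposite
#' sign), node vs focus by the sign of the discriminant, stable vs unstable
#' by the dominant real part.  A conjugate pair whose real part is within
#' \code{neutral_tol} of zero is a neutral center -- the structural regime
#' of conservative LV dynamics.  Real eigenvalues within tolerance of zero
#' (a transcritical crossing) are reported on their stable/unstable side,
#' never as neutral.
#'
#' @param eig a \code{cr_eigen} (or a 2x2 matrix, classified via
#'   \code{\link{eigen_pair}}).
#' @param neutral_tol absolute tolerance (time^-1) on the dominant real
#'   part; default \code{1e-9}.
#' @return one of \code{"stable_node"}, \code{"stable_focus"},
#'   \code{"neutral_center"}, \code{"unstable_focus"},
#'   \code{"unstable_node"}, \code{"saddle"}.
#' @export
classify_regime <- function(eig, neutral_tol = 1e-9) {
  if (is.matrix(eig)) eig <- eigen_pair(eig)
  if (!inherits(eig, "cr_eigen")) stop("eig must be a cr_eigen or matrix")
  r1 <- Re(eig$lambda1); r2 <- Re(eig$lambda2)
  complex_pair <- eig$discriminant < 0
  if (!complex_pair && r1 * r2 < 0) return("saddle")
  if (complex_pair) {
    if (abs(eig$dominant_real) <= neutral_tol) return("neutral_center")
    return(if (eig$dominant_real < 0) "stable_focus" else "unstable_focus")
  }
  if (eig$dominant_real < 0) "stable_node" else "unstable_node"
}
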