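#' Analytic Jacobian of a model variant at an equilibrium
#'
#' Evaluates the closed-form 2x2 Jacobian elements (no finite differences).
#' The equilibrium is verified first: the right-hand side at
#' \code{(A*, Z*)} must vanish to \code{tol * max(1, A*, Z*)}, otherwise a
#' stale-equilibrium error is raised (e.g. an equilibrium computed for
#' different parameter values).
#'
#' At an interior equilibrium the fully linear LV-dynamics systems have
#' \code{J11 = J22 = 0} exactly (per-capita growth is zero there), except
#' that the chemostat influx of RMS_LV shifts \code{J11} to
#' \code{-lK/A*}.
#'
#' @inheritParams cr_rhs
#' @param eq a \code{\link{cr_equilibrium}} or numeric \code{c(A, Z)}.
#' @param check verify the equilibrium residual (default TRUE).
#' @param tol relative residual tolerance for the check.
#' @return 2x2 numeric matrix.
#' @examples
#' p <- cr_params()
#' eqs <- closed_form_equilibria("LV", p)
#' cr_jacobian("LV", p, eqs[[1]])   # trace 0, det m (r - l)
#' @export
cr_jacobian <- function(variant, params, eq, check = TRUE, tol = 1e-8) {
  check_variant(variant)
  st <- as_state(eq)
  if (check) {
    res <- max(abs(cr_rhs(variant, params, st)))
    if (res > tol * max(1, st[1L], st[2L]))
      stop("stale equilibrium: RHS residual ", signif(res, 3),
           " exceeds tolerance for variant ", variant)
  }
  A <- st[1L]; Z <- st[2L]
  v <- pack_params(variant, params)
  r <- v[1]; K <- v[2]; g <- v[3]; a <- v[4]; l <- v[5]; e <- v[6]
  m <- v[7]; Fv <- v[8]; z <- v[9]; rl <- v[10]; gl <- v[11]; Fl <- v[12]
  h2  <- A / (A + a)                 # Holling II response
  dh2 <- a / (A + a)^2               # its derivative
  J <- switch(variant,
    LV = c(r - g * Z - l, -g * A,
           e * g * Z, e * g * A - m),
    LVV = c(r * (1 - 2 * A / K) - g * Z - l, -g * A,
            e * g * Z, e * g * A - m),
    RM = c(r * (1 - 2 * A / K) - g * Z * dh2 - l, -g * h2,
           e * g * Z * dh2, e * g * h2 - m),
    RMS = c(r * (1 - 2 * A / K) - g * Z * dh2 - l, -g * h2,
            e * g * Z * dh2,
            e * g * h2 - m - 2 * Fv * Z * z^2 / (Z^2 + z^2)^2),
    LVV_LV = c(rl - g * Z - l, -g * A,
               e * g * Z, e * g * A - m),
    RM_LV = c(rl - gl * Z - l, -gl * A,
              e * gl * Z, e * gl * A - m),
    RM_LVV = c(r * (1 - 2 * A / K) - gl * Z - l, -gl * A,
               e * gl * Z, e * gl * A - m),
    RMS_LV = c(rl - gl * Z - l, -gl * A,
               e * gl * Z, e * gl * A - m - Fl),
    RMS_LVV = c(r * (1 - 2 * A / K) - gl * Z - l, -gl * A,
                e * gl * Z, e * gl * A - m - Fl),
    RMS_RM = c(r * (1 - 2 * A / K) - g * Z * dh2 - l, -g * h2,
               e * g * Z * dh2, e * g * h2 - m - Fl))
  matrix(J, 2L, 2L, byrow = TRUE,
         dimnames = list(c("A", "Z"), c("A", "Z")))
}
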