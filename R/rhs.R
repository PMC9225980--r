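#' Right-hand side of a consumer-resource model
#'
#' Evaluates the instantaneous derivatives (dA/dt, dZ/dt) of any of the ten
#' model variants.  Nonlinear variants take a \code{\link{cr_params}}
#' object; linearized variants take the \code{cr_linsys} returned by
#' \code{\link{linearize}}.
#'
#' The RMS family carries the chemostat influx \code{+lK} in the resource
#' equation; all its linearizations retain it.
#'
#' @param variant a tag from \code{\link{model_variants}}.
#' @param params \code{cr_params} or \code{cr_linsys}, matching the variant.
#' @param state numeric of length 2, \code{c(A, Z)}, both finite and >= 0.
#' @return numeric of length 2: \code{c(dA_dt, dZ_dt)}.
#' @examples
#' p <- cr_params()
#' cr_rhs("LV", p, c(0.625, 1.225))   # interior LV equilibrium: c(0, 0)
#' @export
cr_rhs <- function(variant, params, state) {
  check_variant(variant)
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("state must be two finite numbers c(A, Z)")
  if (any(state < 0)) stop("negative state is outside the model domain")
  A <- state[[1L]]; Z <- state[[2L]]
  v <- pack_params(variant, params)
  r <- v[1]; K <- v[2]; g <- v[3]; a <- v[4]; l <- v[5]; e <- v[6]
  m <- v[7]; Fv <- v[8]; z <- v[9]; rl <- v[10]; gl <- v[11]; Fl <- v[12]
  switch(variant,
    LV = c(r * A - g * Z * A - l * A,
           e * g * Z * A - m * Z),
    LVV = c(r * A * (1 - A / K) - g * Z * A - l * A,
            e * g * Z * A - m * Z),
    RM = c(r * A * (1 - A / K) - g * Z * A / (A + a) - l * A,
           e * g * Z * A / (A + a) - m * Z),
    RMS = c(r * A * (1 - A / K) - g * Z * A / (A + a) - l * A + l * K,
            e * g * Z * A / (A + a) - m * Z - Fv * Z^2 / (Z^2 + z^2)),
    LVV_LV = c(rl * A - g * Z * A - l * A,
               e * g * Z * A - m * Z),
    RM_LV = c(rl * A - gl * Z * A - l * A,
              e * gl * Z * A - m * Z),
    RM_LVV = c(r * A * (1 - A / K) - gl * Z * A - l * A,
               e * gl * Z * A - m * Z),
    RMS_LV = c(rl * A - gl * Z * A - l * A + l * K,
               e * gl * Z * A - m * Z - Fl * Z),
    RMS_LVV = c(r * A * (1 - A / K) - gl * Z * A - l * A + l * K,
                e * gl * Z * A - m * Z - Fl * Z),
    RMS_RM = c(r * A * (1 - A / K) - g * Z * A / (A + a) - l * A + l * K,
               e * g * Z * A / (A + a) - m * Z - Fl * Z))
}
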