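#' Integrate a trajectory of any model variant
#'
#' Adaptive Dormand-Prince 5(4) integration (compiled; relative tolerance
#' \code{1e-8} by default), sampled on a uniform output grid.  Used by the
#' phase portraits and by the attractor probes behind the global-bifurcation
#' detection.
#'
#' @inheritParams cr_rhs
#' @param init initial state \code{c(A, Z)}, non-negative.
#' @param horizon integration time (model time units).
#' @param dt_out output sampling interval (default 0.2).
#' @param rtol,atol integration tolerances.
#' @param t0 start time (default 0).
#' @return data frame of class \code{cr_trajectory} with columns
#'   \code{time}, \code{A}, \code{Z}.
#' @examples
#' p <- cr_params(K = 5)
#' tr <- trajectory("RM", p, c(1.2, 1.5), horizon = 200)
#' @export
trajectory <- function(variant, params, init, horizon, dt_out = 0.2,
                       rtol = 1e-8, atol = 1e-10, t0 = 0) {
  check_variant(variant)
  init <- as_state(init)
  if (any(init < 0)) stop("initial state must be non-negative")
  if (horizon <= 0) stop("horizon must be positive")
  times <- seq(t0, t0 + horizon, by = dt_out)
  y <- integrate_cr_cpp(variant_code(variant), pack_params(variant, params),
                        init, times, rtol, atol)
  structure(data.frame(time = times, A = y[, 1L], Z = y[, 2L]),
            class = c("cr_trajectory", "data.frame"))
}
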