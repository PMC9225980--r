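#' @title Equilibrium objects
#' @description Constructor for a fixed point of a consumer-resource model.
#'   \code{interior} records feasibility of the consumer (\code{Z_star > 0});
#'   infeasible interior solutions are kept, flagged, so that transcritical
#'   detection can bisect on the sign of \code{Z_star}.
#' @param A_star,Z_star equilibrium densities.
#' @param branch_id small integer distinguishing coexisting solutions
#'   (RMS can have up to three, labelled in order of increasing
#'   \code{A_star}).
#' @param interior logical; defaults to \code{Z_star > 0}.
#' @return an object of class \code{cr_equilibrium}.
#' @export
cr_equilibrium <- function(A_star, Z_star, branch_id = 1L,
                           interior = Z_star > 0) {
  stopifnot(is.finite(A_star), is.finite(Z_star), A_star >= 0)
  structure(list(A_star = A_star, Z_star = Z_star,
                 interior = isTRUE(interior), branch_id = as.integer(branch_id)),
            class = "cr_equilibrium")
}

#' @export
print.cr_equilibrium <- function(x, ...) {
  cat(sprintf("<cr_equilibrium> A*=%.6g Z*=%.6g branch=%d%s\n",
              x$A_star, x$Z_star, x$branch_id,
              if (x$interior) "" else " (infeasible)"))
  invisible(x)
}

as_state <- function(eq) {
  if (inherits(eq, "cr_equilibrium")) c(eq$A_star, eq$Z_star)
  else if (is.numeric(eq) && length(eq) == 2L) as.numeric(eq)
  else stop("expected a cr_equilibrium or a numeric c(A, Z)")
}

#' Closed-form equilibria
#'
#' Returns the interior equilibrium (flagged infeasible when the consumer
#' density is non-positive) plus the consumer-free boundary equilibrium, for
#' every variant that admits explicit expressions.  The RMS family does not
#' (its interior equilibria solve a cubic-like scalar equation); use
#' \code{\link{numeric_equilibria_rms}} for RMS itself, while its linearized
#' counterparts carry their parent equilibrium by construction (see
#' \code{\link{equilibria}}).
#'
#' @param variant one of LV, LVV, RM, LVV_LV, RM_LV, RM_LVV.
#' @param params \code{cr_params} (nonlinear) or \code{cr_linsys}
#'   (linearized variants).
#' @return list of \code{\link{cr_equilibrium}}; the interior equilibrium
#'   first, then the boundary state.
#' @examples
#' closed_form_equilibria("LV", cr_params())      # A* = 0.625, Z* = 1.225
#' @export
closed_form_equilibria <- function(variant, params) {
  check_variant(variant)
  if (parent_variant(variant) == "RMS")
    stop("no closed form for the RMS family; use numeric_equilibria_rms() ",
         "or, for linearized counterparts, the stored parent equilibrium")
  lin <- is_linearized(variant)
  p <- if (lin) params$params else params
  if (lin && !inherits(params, "cr_linsys"))
    stop("linearized variants require a cr_linsys (see linearize())")
  if (!inherits(p, "cr_params")) stop("invalid params object")

  out <- switch(variant,
    LV = {
      A <- p$m / (p$e * p$g)
      Z <- (p$r - p$l) / p$g
      list(cr_equilibrium(A, Z), cr_equilibrium(0, 0, branch_id = 0L))
    },
    LVV = {
      A <- p$m / (p$e * p$g)
      Z <- (p$r * (1 - A / p$K) - p$l) / p$g
      list(cr_equilibrium(A, Z),
           cr_equilibrium(max(p$K * (1 - p$l / p$r), 0), 0, branch_id = 0L))
    },
    RM = {
      if (p$e * p$g <= p$m)
        stop("RM interior equilibrium requires e*g > m")
      A <- p$a * p$m / (p$e * p$g - p$m)
      Z <- (p$r * (1 - A / p$K) - p$l) * (A + p$a) / p$g
      list(cr_equilibrium(A, Z),
           cr_equilibrium(max(p$K * (1 - p$l / p$r), 0), 0, branch_id = 0L))
    },
    LVV_LV = {
      A <- p$m / (p$e * p$g)
      Z <- (params$r_lin - p$l) / p$g
      list(cr_equilibrium(A, Z), cr_equilibrium(0, 0, branch_id = 0L))
    },
    RM_LV = {
      A <- p$m / (p$e * params$g_lin)
      Z <- (params$r_lin - p$l) / params$g_lin
      list(cr_equilibrium(A, Z), cr_equilibrium(0, 0, branch_id = 0L))
    },
    RM_LVV = {
      A <- p$m / (p$e * params$g_lin)
      Z <- (p$r * (1 - A / p$K) - p$l) / params$g_lin
      list(cr_equilibrium(A, Z),
           cr_equilibrium(max(p$K * (1 - p$l / p$r), 0), 0, branch_id = 0L))
    })
  out
}

# consumer density on the resource nullcline of the RMS model,
# Z(A) = [rA(1 - A/K) - lA + lK] (A + a) / (gA); influx = FALSE drops +lK
# (turning the reduction into the plain RM resource equation).
rms_Z_of_A <- function(params, A, influx = TRUE) {
  p <- params
  inf <- if (influx) p$l * p$K else 0
  (p$r * A * (1 - A / p$K) - p$l * A + inf) * (A + p$a) / (p$g * A)
}

# scalar residual of the consumer equation after substituting Z(A);
# interior equilibria are its roots with Z(A) > 0.
rms_residual <- function(params, A, influx = TRUE) {
  p <- params
  Z <- rms_Z_of_A(p, A, influx)
  p$e * p$g * A / (A + p$a) - p$m - p$F * Z / (Z^2 + p$z^2)
}

#' Interior equilibria of the RMS model by scalar root scanning
#'
#' Substitutes the resource-nullcline expression \code{Z(A)} into the
#' consumer equation, yielding one scalar residual in \code{A}.  The
#' residual is scanned on a log-spaced grid, sign changes are bracketed and
#' polished, and near-tangent root pairs (relevant close to a fold, where
#' two equilibria collide) are recovered by locating the interior extrema of
#' the residual.  For parameter sets near the reference values the count of
#' interior equilibria is 1 or 3.
#'
#' @param params a \code{\link{cr_params}} object (the gradient parameter
#'   \code{F} is taken from it).
#' @param search_interval range of \code{A} scanned; default
#'   \code{c(1e-6, 1.5 * K)} (parameter sets near the reference values never place interior
#'   equilibria outside it, since the consumer dies before \code{A}
#'   exceeds \code{K}).
#' @param n_grid number of log-spaced scan points (default 2000).
#' @param influx keep the chemostat influx \code{+lK} (default TRUE).
#'   Setting \code{FALSE} together with \code{F = 0} reduces the system to
#'   the RM model, which is used as an internal cross-check against the RM
#'   closed form.
#' @param variant only \code{"RMS"} is accepted; the linearized RMS
#'   counterparts have at most one interior equilibrium, available through
#'   \code{\link{equilibria}}.
#' @return list of interior \code{\link{cr_equilibrium}}, deduplicated,
#'   sorted by \code{A_star} and branch-labelled 1..n; empty list (with a
#'   warning) when no sign change is found.
#' @export
numeric_equilibria_rms <- function(params, search_interval = NULL,
                                   n_grid = 2000L, influx = TRUE,
                                   variant = "RMS") {
  if (!identical(variant, "RMS"))
    stop("numeric_equilibria_rms() solves the nonlinear RMS system only")
  if (!inherits(params, "cr_params")) stop("params must be cr_params")
  if (is.null(search_interval)) search_interval <- c(1e-6, 1.5 * params$K)
  if (any(search_interval <= 0) || diff(search_interval) <= 0)
    stop("search interval must be positive and increasing")
  # extra linear resolution below A = K: the consumer branch can sit in a
  # narrow sliver just under the carrying capacity (Z -> 0 there), which a
  # log-spaced grid alone can step over
  extra <- if (params$K > search_interval[1L])
    seq(max(0.5 * params$K, search_interval[1L]),
        min(1.05 * params$K, search_interval[2L]), length.out = n_grid)
  else numeric(0)
  roots <- scan_roots(function(A) {
    Z <- rms_Z_of_A(params, A, influx)
    ifelse(Z > 0, rms_residual(params, A, influx), NA_real_)
  }, search_interval, n_grid, extra = extra)
  if (!length(roots)) {
    warning("no interior equilibrium found in the search interval")
    return(list())
  }
  roots <- sort(roots)
  keep <- c(TRUE, diff(roots) / pmax(roots[-length(roots)], 1) > 1e-8)
  roots <- roots[keep]
  lapply(seq_along(roots), function(i)
    cr_equilibrium(roots[i], rms_Z_of_A(params, roots[i], influx),
                   branch_id = i))
}

# All roots of f on (lo, hi): log-spaced scan + bisection-polish of sign
# changes, plus an extremum sweep that splits near-tangent pairs which the
# grid alone would miss close to a fold.
scan_roots <- function(f, interval, n_grid, extra = numeric(0)) {
  xs <- sort(unique(c(
    exp(seq(log(interval[1L]), log(interval[2L]), length.out = n_grid)),
    extra)))
  n_grid <- length(xs)
  fs <- f(xs)                     # residuals are vectorized in A
  if (length(fs) != length(xs)) fs <- vapply(xs, f, numeric(1))
  ok <- is.finite(fs)
  roots <- numeric(0)
  polish <- function(lo, hi)
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  for (i in seq_len(n_grid - 1L)) {
    if (ok[i] && ok[i + 1L] && fs[i] * fs[i + 1L] < 0)
      roots <- c(roots, polish(xs[i], xs[i + 1L]))
    else if (ok[i] && fs[i] == 0) roots <- c(roots, xs[i])
  }
  # interior extrema of f: a local min (max) with value of opposite sign to
  # its neighbourhood indicates a just-separated root pair
  for (i in 2:(n_grid - 1L)) {
    if (!(ok[i - 1L] && ok[i] && ok[i + 1L])) next
    s <- sign(fs[i])
    if (s == 0) next
    if (abs(fs[i]) < abs(fs[i - 1L]) && abs(fs[i]) < abs(fs[i + 1L]) &&
        sign(fs[i - 1L]) == s && sign(fs[i + 1L]) == s) {
      opt <- optimize(f, c(xs[i - 1L], xs[i + 1L]), maximum = s < 0,
                      tol = 1e-12)
      xext <- if (s < 0) opt$maximum else opt$minimum
      fext <- if (s < 0) opt$objective else opt$objective
      if (is.finite(fext) && sign(fext) == -s) {
        roots <- c(roots, polish(xs[i - 1L], xext), polish(xext, xs[i + 1L]))
      }
    }
  }
  sort(unique(roots))
}

#' Equilibria of any model variant
#'
#' Dispatcher: closed forms where they exist, the numeric scalar-reduction
#' solver for RMS, and the stored parent equilibrium for linearized RMS
#' counterparts (which preserve it exactly by construction).
#'
#' @inheritParams closed_form_equilibria
#' @param interior_only drop boundary (consumer-free) states; default FALSE.
#' @return list of \code{\link{cr_equilibrium}}.
#' @export
equilibria <- function(variant, params, interior_only = FALSE) {
  check_variant(variant)
  eqs <- if (variant == "RMS") {
    numeric_equilibria_rms(params)
  } else if (is_linearized(variant) && parent_variant(variant) == "RMS") {
    if (!inherits(params, "cr_linsys")) stop("need a cr_linsys")
    list(params$parent_equilibrium)
  } else {
    closed_form_equilibria(variant, params)
  }
  if (interior_only)
    eqs <- Filter(function(e) e$interior, eqs)
  eqs
}
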