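#' Bifurcation event objects
#'
#' @param kind one of \code{"transcritical"}, \code{"hopf"}, \code{"fold"},
#'   \code{"homoclinic"}.
#' @param param_value location of the event in gradient-parameter units.
#' @param branch_id branch the event was detected on.
#' @param refinement_tol width of the final bisection bracket.
#' @return object of class \code{cr_event}.
#' @export
cr_event <- function(kind, param_value, branch_id = 1L,
                     refinement_tol = NA_real_) {
  kind <- match.arg(kind, c("transcritical", "hopf", "fold", "homoclinic"))
  structure(list(kind = kind, param_value = param_value,
                 branch_id = as.integer(branch_id),
                 refinement_tol = refinement_tol),
            class = "cr_event")
}

#' @export
print.cr_event <- function(x, ...) {
  cat(sprintf("<cr_event> %s at %s = %.6g (branch %d, tol %.2g)\n",
              x$kind, "param", x$param_value, x$branch_id,
              x$refinement_tol))
  invisible(x)
}

#' Write a list of bifurcation events as JSON
#' @param events list of \code{\link{cr_event}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_events_json <- function(events, path) {
  obj <- lapply(events, function(ev)
    list(kind = ev$kind, param_value = ev$param_value,
         branch_id = ev$branch_id, refinement_tol = ev$refinement_tol))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# sign quantity for the transcritical threshold: the consumer density of
# the (possibly infeasible) interior branch of `variant` at gradient value v
interior_Z_sign <- function(variant, params, name, v) {
  p <- set_param(params, name, v)
  if (!is_linearized(variant)) {
    eqs <- closed_form_equilibria(variant, p)
    return(eqs[[1L]]$Z_star)
  }
  parent <- parent_variant(variant)
  peq <- closed_form_equilibria(parent, p)[[1L]]
  peq_obj <- cr_equilibrium(peq$A_star, max(peq$Z_star, 0),
                            interior = TRUE)
  lin <- linearize_unchecked(parent, p, peq_obj, target_dynamics(variant))
  # interior consumer equilibrium of the linearized system itself
  switch(variant,
         LVV_LV = (lin$r_lin - p$l) / p$g,
         RM_LV = (lin$r_lin - p$l) / lin$g_lin,
         RM_LVV = {
           A <- p$m / (p$e * lin$g_lin)
           (p$r * (1 - A / p$K) - p$l) / lin$g_lin
         },
         stop("no transcritical structure implemented for ", variant))
}

#' Detect the predator invasion threshold (transcritical bifurcation)
#'
#' Locates the gradient value at which the interior consumer equilibrium
#' crosses zero.  For the nonlinear LVV and RM models the closed form
#' \eqn{K = A^* / (1 - l/r)} (with \eqn{A^*} the consumer-set resource
#' level) is used; for linearized counterparts the counterpart system is
#' rebuilt at every trial value and its own interior consumer branch is
#' bisected on sign.
#'
#' @param variant LVV, RM, or one of their linearized counterparts.
#' @param params \code{\link{cr_params}}.
#' @param grad a \code{\link{gradient_spec}} over \code{K}.
#' @param refine_tol bisection bracket width (parameter units).
#' @return a \code{\link{cr_event}} of kind \code{"transcritical"}.
#' @examples
#' detect_transcritical("LVV", cr_params(), gradient_spec("K"))  # K = 0.638
#' @export
detect_transcritical <- function(variant, params, grad = gradient_spec("K"),
                                 refine_tol = 1e-6) {
  check_variant(variant)
  if (!inherits(grad, "cr_gradient")) stop("grad must be a gradient_spec()")
  if (grad$parameter != "K" || parent_variant(variant) %in% c("LV", "RMS"))
    stop("transcritical detection not available: no interior consumer ",
         "sign change for '", variant, "' along ", grad$parameter)
  if (variant %in% c("LVV", "RM")) {
    p <- params
    A <- if (variant == "LVV") p$m / (p$e * p$g) else
      p$a * p$m / (p$e * p$g - p$m)
    Kc <- A / (1 - p$l / p$r)
    if (Kc < grad$lo || Kc > grad$hi)
      stop("closed-form threshold ", signif(Kc, 6),
           " lies outside the gradient range")
    return(cr_event("transcritical", Kc, 1L, refinement_tol = 0))
  }
  lo <- max(grad$lo, 1e-9); hi <- grad$hi
  f <- function(v) interior_Z_sign(variant, params, grad$parameter, v)
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no sign change of the interior consumer equilibrium in range")
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    if (f(mid) * flo > 0) { lo <- mid; flo <- f(mid) } else hi <- mid
  }
  cr_event("transcritical", (lo + hi) / 2, 1L, refinement_tol = refine_tol)
}

# dominant eigenvalue (and discriminant) of `variant` on the branch_id-th
# lowest-A feasible interior equilibrium at gradient value v; NAs when the
# branch is absent
branch_eigen <- function(variant, params, name, v, branch_id) {
  p <- tryCatch(set_param(params, name, v), error = function(e) NULL)
  if (is.null(p)) return(c(re = NA_real_, disc = NA_real_))
  eqs <- interior_at(variant, p)
  if (length(eqs) < branch_id) return(c(re = NA_real_, disc = NA_real_))
  st <- tryCatch(stability_at(variant, p, eqs[[branch_id]]),
                 error = function(e) NULL)
  if (is.null(st)) return(c(re = NA_real_, disc = NA_real_))
  c(re = st$dominant_real, disc = st$discriminant)
}

#' Detect a Hopf bifurcation along a gradient
#'
#' Scans the dominant eigenvalue's real part along the chosen equilibrium
#' branch, requires a sign change flanked by complex (oscillatory)
#' eigenvalues, and refines it by bisection.  Sign changes with real
#' eigenvalues are not Hopf points (they accompany folds or transcritical
#' crossings) and are skipped.
#'
#' @inheritParams detect_transcritical
#' @param grad gradient over \code{K} or \code{F}.
#' @param branch_id which branch (1 = lowest \code{A_star}); the RMS
#'   oscillatory branch is branch 1.
#' @return a \code{\link{cr_event}} of kind \code{"hopf"}.
#' @examples
#' \donttest{
#' detect_hopf("RM", cr_params(), gradient_spec("K"))     # K = 2.653
#' }
#' @export
detect_hopf <- function(variant, params, grad, branch_id = 1L,
                        refine_tol = 1e-6) {
  check_variant(variant)
  if (!inherits(grad, "cr_gradient")) stop("grad must be a gradient_spec()")
  vals <- grad_values(grad)
  ev <- vapply(vals, function(v)
    branch_eigen(variant, params, grad$parameter, v, branch_id),
    numeric(2))
  re <- ev[1L, ]; disc <- ev[2L, ]
  for (i in seq_len(length(vals) - 1L)) {
    if (!is.finite(re[i]) || !is.finite(re[i + 1L])) next
    if (re[i] * re[i + 1L] >= 0) next
    # neutral centers: a sign flip at roundoff magnitude is not a crossing
    if (abs(re[i]) < 1e-12 && abs(re[i + 1L]) < 1e-12) next
    if (!(disc[i] < 0 && disc[i + 1L] < 0)) next  # real crossing: not Hopf
    lo <- vals[i]; hi <- vals[i + 1L]
    rlo <- re[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      rmid <- branch_eigen(variant, params, grad$parameter, mid,
                           branch_id)[["re"]]
      if (!is.finite(rmid)) break
      if (rmid * rlo > 0) { lo <- mid; rlo <- rmid } else hi <- mid
    }
    return(cr_event("hopf", (lo + hi) / 2, branch_id,
                    refinement_tol = refine_tol))
  }
  stop("no Hopf bifurcation found for '", variant, "' on branch ",
       branch_id, " in the gradient range (a stability window narrower ",
       "than the grid spacing needs a larger n_points)")
}

#' Detect fold (saddle-node) bifurcations along a gradient
#'
#' Folds are located as parameter values where the number of interior
#' equilibria changes, refined by bisection on the count.  Only the
#' nonlinear RMS model has the cubic equilibrium structure that produces
#' folds; every other variant (including the linearized RMS counterparts,
#' whose interaction terms are monotone in the state) has a single interior
#' branch and returns an empty list.
#'
#' @inheritParams detect_hopf
#' @return list of \code{\link{cr_event}} of kind \code{"fold"}, sorted by
#'   parameter value (empty when the branch count never changes).
#' @examples
#' \donttest{
#' detect_fold("RMS", cr_params(K = 10), gradient_spec("F"))
#' # folds near F = 0.0759 and F = 0.2408
#' }
#' @export
detect_fold <- function(variant, params, grad, refine_tol = 1e-5) {
  check_variant(variant)
  if (!inherits(grad, "cr_gradient")) stop("grad must be a gradient_spec()")
  if (variant != "RMS") return(list())
  vals <- grad_values(grad)
  cnt <- function(v)
    length(suppressWarnings(
      numeric_equilibria_rms(set_param(params, grad$parameter, v))))
  counts <- vapply(vals, cnt, integer(1))
  events <- list()
  for (i in seq_len(length(vals) - 1L)) {
    if (counts[i] == counts[i + 1L]) next
    lo <- vals[i]; hi <- vals[i + 1L]; clo <- counts[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      if (cnt(mid) == clo) lo <- mid else hi <- mid
    }
    events <- c(events, list(cr_event("fold", (lo + hi) / 2,
                                      branch_id = max(counts[i], counts[i + 1L]),
                                      refinement_tol = refine_tol)))
  }
  events[order(vapply(events, `[[`, numeric(1), "param_value"))]
}

#' Probe the attractor reached from a displaced equilibrium
#'
#' Integrates the full (nonlinear or counterpart) system from a state
#' displaced by a small relative amount from the given interior equilibrium
#' and classifies the late-time behaviour: convergence back to the
#' equilibrium, a sustained bounded oscillation (successive consumer peaks
#' converging to a common nonzero amplitude), or convergence to a different
#' equilibrium.  When the transient has not resolved within the horizon the
#' integration is continued (doubling) up to \code{max_doublings} times.
#'
#' @inheritParams cr_rhs
#' @param eq interior \code{\link{cr_equilibrium}} to displace from.
#' @param horizon integration time per attempt (default 5000).
#' @param displacement relative displacement of both state components
#'   (default 1\%).
#' @param dt_out output sampling step for the peak analysis.
#' @param rtol,atol integrator tolerances.
#' @param max_doublings extra integration rounds for slow transients.
#' @return one of \code{"settles_to_eq"}, \code{"limit_cycle"},
#'   \code{"other_attractor"}.
#' @examples
#' \donttest{
#' p <- cr_params(K = 5)
#' eq <- closed_form_equilibria("RM", p)[[1]]
#' attractor_probe("RM", p, eq)     # "limit_cycle"
#' }
#' @export
attractor_probe <- function(variant, params, eq, horizon = 5000,
                            displacement = 0.01, dt_out = 0.2,
                            rtol = 1e-8, atol = 1e-10, max_doublings = 3L) {
  check_variant(variant)
  if (!inherits(eq, "cr_equilibrium") || !eq$interior)
    stop("eq must be a feasible interior equilibrium")
  scale <- max(1, eq$A_star, eq$Z_star)
  others <- if (!is_linearized(variant))
    tryCatch(suppressWarnings(equilibria(variant, params,
                                         interior_only = TRUE)),
             error = function(e) list())
  else list()
  others <- Filter(function(o) abs(o$A_star - eq$A_star) > 1e-6 * scale,
                   others)
  state <- as_state(eq) * (1 + displacement)
  t0 <- 0
  horiz <- horizon
  for (round in 0:max_doublings) {
    tr <- trajectory(variant, params, state, horiz, dt_out = dt_out,
                     rtol = rtol, atol = atol, t0 = t0)
    n <- nrow(tr)
    tail_df <- tr[(n %/% 2):n, ]
    devA <- abs(tail_df$A - eq$A_star)
    devZ <- abs(tail_df$Z - eq$Z_star)
    if (max(devA, devZ) < 1e-3 * scale) return("settles_to_eq")
    rngA <- diff(range(tail_df$A)); rngZ <- diff(range(tail_df$Z))
    if (max(rngA, rngZ) < 1e-3 * scale) {
      fin <- c(tail_df$A[nrow(tail_df)], tail_df$Z[nrow(tail_df)])
      for (o in others) {
        if (max(abs(fin - as_state(o))) < 1e-2 * max(1, o$A_star, o$Z_star))
          return("other_attractor")
      }
      # flat but not at a known equilibrium: treat as settled elsewhere
      return("other_attractor")
    }
    z <- tail_df$Z
    pk <- which(z[-c(1L, length(z))] > z[-c(length(z) - 1L, length(z))] &
                  z[-c(1L, length(z))] >= z[-(1:2)]) + 1L
    if (length(pk) >= 5L) {
      last5 <- z[pk[(length(pk) - 4L):length(pk)]]
      if (diff(range(last5)) < 0.01 * abs(mean(last5)) &&
          max(rngA, rngZ) > 1e-3)
        return("limit_cycle")
    }
    # unresolved transient: continue from the final state
    state <- c(tr$A[n], tr$Z[n])
    t0 <- t0 + horiz
    horiz <- horiz * 2
  }
  warning("attractor probe did not resolve; classifying by last window")
  if (length(pk) >= 2L) "limit_cycle" else "other_attractor"
}

#' Detect the homoclinic (global bifurcation) window of the RMS model
#'
#' Local eigenvalue analysis cannot see the destruction of the RMS limit
#' cycle on the saddle.  The two boundaries of the window are therefore
#' located by trajectory classification: along the oscillatory (lowest
#' \code{A_star}) branch, \code{\link{attractor_probe}} distinguishes a
#' sustained limit cycle from a shift to the alternative stable state, and
#' the boundary of limit-cycle existence is bisected in \code{F} from both
#' sides of the window.
#'
#' Near the Hopf point the limit cycle is tiny, so the probes here displace
#' by 0.1\% (a 1\% displacement would start outside the newly born cycle
#' and jump the separatrix) and integrate long horizons.
#'
#' @param params \code{\link{cr_params}} (with the intended \code{K}).
#' @param grad gradient over \code{F}.
#' @param refine_tol bisection bracket width in \code{F} (default
#'   \code{5e-5}, resolving the fourth decimal).
#' @param displacement relative displacement used by the probes.
#' @param horizon probe integration time.
#' @param folds,hopf optionally pass precomputed \code{\link{detect_fold}} /
#'   \code{\link{detect_hopf}} events to avoid recomputation.
#' @return list of two \code{\link{cr_event}}s of kind \code{"homoclinic"}
#'   (lower and upper boundary).
#' @examples
#' \donttest{
#' detect_global(cr_params(K = 10), gradient_spec("F"))
#' # boundaries near F = 0.0784 and F = 0.2401
#' }
#' @export
detect_global <- function(params, grad = gradient_spec("F"),
                          refine_tol = 5e-5, displacement = 0.001,
                          horizon = 40000, folds = NULL, hopf = NULL) {
  if (!inherits(grad, "cr_gradient") || grad$parameter != "F")
    stop("detect_global needs a gradient over F")
  if (is.null(folds)) folds <- detect_fold("RMS", params, grad)
  if (length(folds) < 2L)
    stop("expected a bistable window (two folds) in the gradient range")
  if (is.null(hopf)) hopf <- detect_hopf("RMS", params, grad, branch_id = 1L)
  fold_lo <- folds[[1L]]$param_value
  f_hopf <- hopf$param_value
  probe <- function(Fv) {
    p <- set_param(params, "F", Fv)
    eqs <- interior_at("RMS", p)
    if (!length(eqs)) stop("no interior equilibrium at F = ", Fv)
    attractor_probe("RMS", p, eqs[[1L]], horizon = horizon,
                    displacement = displacement, max_doublings = 2L)
  }
  cycle_like <- function(out) out %in% c("limit_cycle", "settles_to_eq")
  mid <- (fold_lo + f_hopf) / 2
  if (cycle_like(probe(mid)))
    stop("no attractor contrast across the window: probe at F = ",
         signif(mid, 4), " already sustains a cycle")
  find_edge <- function(candidates) {
    for (Fv in candidates) if (cycle_like(probe(Fv))) return(Fv)
    stop("could not bracket the homoclinic boundary: no limit cycle ",
         "found near the window edge")
  }
  lower_left <- find_edge(fold_lo + c(1e-3, 5e-4, 2e-3))
  upper_right <- find_edge(f_hopf - c(2e-4, 1e-4, 4e-4))
  bisect <- function(lo, hi, cycle_at_lo) {
    while (hi - lo > refine_tol) {
      midv <- (lo + hi) / 2
      if (cycle_like(probe(midv)) == cycle_at_lo) lo <- midv else hi <- midv
    }
    (lo + hi) / 2
  }
  lower <- bisect(lower_left, mid, cycle_at_lo = TRUE)
  upper <- bisect(mid, upper_right, cycle_at_lo = FALSE)
  list(cr_event("homoclinic", lower, 1L, refinement_tol = refine_tol),
       cr_event("homoclinic", upper, 1L, refinement_tol = refine_tol))
}
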