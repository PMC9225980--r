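#' Equilibrium-preserving linearization of a nonlinear model
#'
#' Replaces nonlinear growth, interaction and loss terms of a parent model
#' by proportional terms whose coefficients are expressed through the
#' parent's interior equilibrium, so that the equilibrium densities and the
#' material fluxes through the equilibrium are unchanged:
#' \deqn{r_{lin} = r (1 - A^*/K), \quad g_{lin} = g/(A^* + a), \quad
#'       F_{lin} = F Z^* / (Z^{*2} + z^2).}
#' Only terms simpler than \code{target} are linearized: target \code{"LV"}
#' linearizes everything, \code{"LVV"} keeps the logistic growth, and
#' \code{"RM"} (parent RMS only) keeps logistic growth and the Holling
#' type II interaction.  The RMS counterparts always retain the chemostat
#' influx \code{+lK}.
#'
#' @param parent_variant one of \code{"LVV"}, \code{"RM"}, \code{"RMS"}.
#' @param params the parent's \code{\link{cr_params}}.
#' @param eq interior \code{\link{cr_equilibrium}} of the parent at these
#'   parameters; linearizing an infeasible equilibrium is refused (the
#'   procedure mimics parameterization from observed, hence existing,
#'   states).
#' @param target dynamics imposed: \code{"LV"}, \code{"LVV"} or \code{"RM"};
#'   must be strictly simpler than the parent.
#' @return an object of class \code{cr_linsys} with fields \code{tag},
#'   \code{r_lin}, \code{g_lin}, \code{F_lin}, \code{retained_terms},
#'   \code{params} (parent parameters) and \code{parent_equilibrium}.
#' @examples
#' p <- cr_params(K = 5)
#' eq <- closed_form_equilibria("RM", p)[[1]]
#' linearize("RM", p, eq, "LV")    # r_lin = 0.4, g_lin = 0.25
#' @export
linearize <- function(parent_variant, params, eq, target = "LV") {
  lin <- linearize_unchecked(parent_variant, params, eq, target)
  if (!eq$interior || eq$Z_star <= 0)
    stop("cannot linearize at an infeasible (Z* <= 0) equilibrium")
  res <- max(abs(cr_rhs(parent_variant, params, as_state(eq))))
  if (res > 1e-8 * max(1, eq$A_star, eq$Z_star))
    stop("eq is not an equilibrium of the parent (residual ",
         signif(res, 3), ")")
  lin
}

# core constructor without feasibility/residual guards; transcritical
# bisection uses it to track the sign of the linearized consumer branch
# across the threshold, where the parent equilibrium is infeasible.
linearize_unchecked <- function(parent_variant, params, eq, target) {
  check_variant(parent_variant)
  if (is_linearized(parent_variant) || parent_variant == "LV")
    stop("parent must be one of LVV, RM, RMS")
  order_ <- c(LV = 1, LVV = 2, RM = 3, RMS = 4)
  if (!(target %in% c("LV", "LVV", "RM")))
    stop("target must be LV, LVV or RM")
  if (order_[[target]] >= order_[[parent_variant]])
    stop("target dynamics '", target, "' is not strictly simpler than ",
         "parent '", parent_variant, "'")
  if (!inherits(params, "cr_params")) stop("params must be cr_params")
  if (!inherits(eq, "cr_equilibrium")) stop("eq must be a cr_equilibrium")
  A <- eq$A_star; Z <- eq$Z_star
  tag <- paste(parent_variant, target, sep = "_")
  retained <- switch(target,
                     LV = character(0),
                     LVV = "logistic",
                     RM = c("logistic", "hollingII"))
  r_lin <- params$r * (1 - A / params$K)
  g_lin <- if (parent_variant == "LVV") params$g else
    params$g / (A + params$a)
  F_lin <- if (parent_variant == "RMS")
    params$F * Z / (Z^2 + params$z^2) else 0
  structure(list(tag = tag, parent_variant = parent_variant,
                 target = target, retained_terms = retained,
                 r_lin = r_lin, g_lin = g_lin, F_lin = F_lin,
                 params = params, parent_equilibrium = eq),
            class = "cr_linsys")
}

#' @export
print.cr_linsys <- function(x, ...) {
  cat(sprintf(
    "<cr_linsys %s>  r_lin=%.6g  g_lin=%.6g  F_lin=%.6g\n  retained: %s;  parent eq A*=%.6g Z*=%.6g\n",
    x$tag, x$r_lin, x$g_lin, x$F_lin,
    if (length(x$retained_terms)) paste(x$retained_terms, collapse = ", ")
    else "none",
    x$parent_equilibrium$A_star, x$parent_equilibrium$Z_star))
  invisible(x)
}

#' Consumption flux of a variant at a state
#'
#' The resource-to-consumer flow per unit time: \code{g Z A} for type I
#' interactions, \code{g Z A/(A+a)} where the Holling type II term is
#' retained.
#'
#' @inheritParams cr_rhs
#' @param state numeric \code{c(A, Z)} or \code{\link{cr_equilibrium}}.
#' @return a single number.
#' @export
consumption_flux <- function(variant, params, state) {
  check_variant(variant)
  st <- as_state(state)
  A <- st[1L]; Z <- st[2L]
  v <- pack_params(variant, params)
  g <- v[3]; a <- v[4]; gl <- v[11]
  if (variant %in% c("RM", "RMS", "RMS_RM")) g * Z * A / (A + a)
  else if (variant %in% c("LV", "LVV")) g * Z * A
  else gl * Z * A
}

#' Preservation diagnostics of a linearized system
#'
#' By construction a linearized counterpart must reproduce its parent's
#' equilibrium and the consumption flux through it exactly.  This returns
#' the residuals: the maximum right-hand-side magnitude of the linearized
#' system at the parent equilibrium, and the absolute consumption-flux
#' mismatch between parent and counterpart there.  Both are zero to
#' numerical roundoff for a valid construction.
#'
#' @param parent_variant the parent tag.
#' @param params the parent's \code{\link{cr_params}}.
#' @param lin a \code{cr_linsys} built from those parameters.
#' @return named numeric: \code{rhs_residual}, \code{flux_mismatch}.
#' @export
preservation_residual <- function(parent_variant, params, lin) {
  if (!inherits(lin, "cr_linsys")) stop("lin must be a cr_linsys")
  eq <- lin$parent_equilibrium
  st <- as_state(eq)
  rhs_res <- max(abs(cr_rhs(lin$tag, lin, st)))
  flux <- abs(consumption_flux(parent_variant, params, st) -
              consumption_flux(lin$tag, lin, st))
  c(rhs_residual = rhs_res, flux_mismatch = flux)
}

#' Write a linearized-parameter report
#'
#' Serializes the linear coefficients, retained terms and parent
#' equilibrium of a \code{cr_linsys} as JSON.
#'
#' @param lin a \code{cr_linsys}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_linsys_json <- function(lin, path) {
  if (!inherits(lin, "cr_linsys")) stop("lin must be a cr_linsys")
  obj <- list(tag = lin$tag, parent = lin$parent_variant,
              target = lin$target,
              r_lin = lin$r_lin, g_lin = lin$g_lin, F_lin = lin$F_lin,
              retained_terms = as.list(lin$retained_terms),
              parent_equilibrium = list(A_star = lin$parent_equilibrium$A_star,
                                        Z_star = lin$parent_equilibrium$Z_star,
                                        branch_id = lin$parent_equilibrium$branch_id))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
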