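#' Sample a virtual observation of biomasses and material fluxes
#'
#' Treats an interior equilibrium of a nonlinear model as a field
#' observation: the standing biomasses and the per-time material fluxes
#' through the equilibrium (net resource production, resource-to-consumer
#' consumption, consumer loss to the top-consumer).  This emulates the
#' empirical information from which observation-based food web models are
#' parameterized.  Optionally each observed quantity receives independent
#' multiplicative lognormal noise \code{exp(sigma * N(0,1))}; at
#' \code{noise_sigma = 0} the observation equals the model's term values
#' exactly and repeated calls are identical.
#'
#' @param variant a nonlinear tag: LV, LVV, RM or RMS.
#' @param params \code{\link{cr_params}}.
#' @param eq interior \code{\link{cr_equilibrium}} of the variant.
#' @param noise_sigma lognormal scale (0 = exact observation).
#' @param seed integer; with noise, draws are fully determined by
#'   \code{(seed, quantity index)} with quantities in the fixed order
#'   A, Z, consumption, production, top-consumer loss.
#' @return object of class \code{cr_observation}.
#' @examples
#' p <- cr_params(K = 5)
#' eq <- closed_form_equilibria("RM", p)[[1]]
#' sample_observation("RM", p, eq)   # consumption_flux = 0.39
#' @export
sample_observation <- function(variant, params, eq, noise_sigma = 0,
                               seed = NULL) {
  check_variant(variant)
  if (is_linearized(variant))
    stop("observations are sampled from the nonlinear models only")
  if (!inherits(eq, "cr_equilibrium") || !eq$interior)
    stop("eq must be a feasible interior equilibrium")
  res <- max(abs(cr_rhs(variant, params, as_state(eq))))
  if (res > 1e-8 * max(1, eq$A_star, eq$Z_star))
    stop("eq is not an equilibrium at these parameters")
  A <- eq$A_star; Z <- eq$Z_star; p <- params
  production <- if (variant == "LV") p$r * A else p$r * A * (1 - A / p$K)
  consumption <- consumption_flux(variant, params, eq)
  top_loss <- if (variant == "RMS") p$F * Z^2 / (Z^2 + p$z^2) else 0
  vals <- c(A_obs = A, Z_obs = Z, consumption_flux = consumption,
            production_flux = production, top_loss_flux = top_loss)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sigma > 0")
    draws <- local({
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(as.integer(seed))
      rnorm(length(vals))
    })
    vals <- vals * exp(noise_sigma * draws)
  }
  structure(c(as.list(vals),
              list(variant = variant, noise_sigma = noise_sigma,
                   seed = if (is.null(seed)) NA_integer_ else
                     as.integer(seed),
                   params = params)),
            class = "cr_observation")
}

#' Fit a fully linear (LV-dynamics) system from a flux observation
#'
#' Recovers the proportional coefficients directly from the observed
#' biomasses and fluxes -- the step by which observation-based food web
#' models obtain per-capita interaction strengths:
#' \code{g_lin = consumption/(A Z)}, \code{r_lin = production/A},
#' \code{F_lin = top_loss/Z}.  With a noise-free observation these equal
#' the equilibrium-preserving linearization of the parent model exactly.
#'
#' @param obs a \code{\link{cr_observation}} from an LVV, RM or RMS model.
#' @param carried parameters carried over unchanged (\code{l, e, m, K} and,
#'   for bookkeeping, the rest); defaults to the parameters stored with the
#'   observation.
#' @return a \code{cr_linsys} with target LV dynamics.
#' @export
fit_linear_from_observation <- function(obs, carried = obs$params) {
  if (!inherits(obs, "cr_observation")) stop("obs must be a cr_observation")
  if (obs$variant == "LV")
    stop("the LV model is already fully linear; nothing to fit")
  if (obs$A_obs <= 0 || obs$Z_obs <= 0)
    stop("observed biomasses must be positive")
  structure(list(tag = paste(obs$variant, "LV", sep = "_"),
                 parent_variant = obs$variant, target = "LV",
                 retained_terms = character(0),
                 r_lin = obs$production_flux / obs$A_obs,
                 g_lin = obs$consumption_flux / (obs$A_obs * obs$Z_obs),
                 F_lin = obs$top_loss_flux / obs$Z_obs,
                 params = carried,
                 parent_equilibrium = cr_equilibrium(obs$A_obs, obs$Z_obs)),
            class = "cr_linsys")
}

#' Serialize / read a flux observation as JSON
#' @param obs a \code{cr_observation}.
#' @param path file path.
#' @return \code{path} (write) or a \code{cr_observation} (read).
#' @export
write_observation_json <- function(obs, path) {
  if (!inherits(obs, "cr_observation")) stop("obs must be a cr_observation")
  obj <- list(variant = obs$variant,
              A_obs = obs$A_obs, Z_obs = obs$Z_obs,
              consumption_flux = obs$consumption_flux,
              production_flux = obs$production_flux,
              top_loss_flux = obs$top_loss_flux,
              noise_sigma = obs$noise_sigma, seed = obs$seed,
              params = unclass(obs$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_observation_json
#' @export
read_observation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(A_obs = obj$A_obs, Z_obs = obj$Z_obs,
                 consumption_flux = obj$consumption_flux,
                 production_flux = obj$production_flux,
                 top_loss_flux = obj$top_loss_flux,
                 variant = obj$variant, noise_sigma = obj$noise_sigma,
                 seed = obj$seed,
                 params = do.call(cr_params, as.list(obj$params))),
            class = "cr_observation")
}
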