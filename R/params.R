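#' Parameters of the nonlinear consumer-resource models
#'
#' Constructs a validated parameter set for the LV/LVV/RM/RMS model family.
#' The defaults are the algae-zooplankton values used throughout the
#' package's reference analyses (the parameterization of Scheffer's
#' consumer-resource work): they are the ones shipped in
#' \code{system.file("extdata", "reference_params.cfg", package = "crstab")}.
#'
#' @param r maximum resource growth rate (time^-1).
#' @param K resource carrying capacity (resource units); gradient range 0-10.
#' @param g maximum consumer intake rate.
#' @param a half-saturation of the consumer on the resource (resource units).
#' @param l resource loss rate (time^-1).
#' @param e consumer-resource conversion efficiency, in (0, 1].
#' @param m consumer loss rate (time^-1).
#' @param F maximum top-consumer intake (consumer units time^-1, >= 0);
#'   gradient range 0-0.3.  Only the RMS family uses it.
#' @param z half-saturation of the top-consumer on the consumer (consumer
#'   units).
#' @return an object of class \code{cr_params} (a named list).
#' @examples
#' p <- cr_params()            # reference values
#' p5 <- cr_params(K = 5)      # enrichment level used in the phase portraits
#' @export
cr_params <- function(r = 0.5, K = 10, g = 0.4, a = 0.6, l = 0.01,
                      e = 0.6, m = 0.15, F = 0, z = 0.5) {
  p <- list(r = r, K = K, g = g, a = a, l = l, e = e, m = m, F = F, z = z)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (p$F < 0 || p$K < 0) stop("F and K must be >= 0")
  strict <- c("r", "g", "a", "l", "e", "m", "z")
  if (any(unlist(p[strict]) <= 0))
    stop("parameters ", paste(strict, collapse = ", "), " must be > 0")
  if (p$e > 1) stop("conversion efficiency e must be <= 1")
  structure(p, class = "cr_params")
}

#' @export
print.cr_params <- function(x, ...) {
  cat("<cr_params> ",
      paste(names(x), signif(unlist(x), 6), sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Read a key=value parameter file
#'
#' Parses a plain-text configuration with one \code{name=value} pair per
#' line (\code{#} starts a comment).  Unknown keys are rejected; missing
#' keys fall back to the \code{\link{cr_params}} defaults.
#'
#' @param path path to the configuration file.
#' @return a \code{\link{cr_params}} object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(x) length(x) != 2L, logical(1))
  if (any(bad)) stop("malformed line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric value for: ",
                        paste(keys[is.na(vals)], collapse = ", "))
  allowed <- names(formals(cr_params))
  if (length(setdiff(keys, allowed)))
    stop("unknown parameter(s): ",
         paste(setdiff(keys, allowed), collapse = ", "))
  do.call(cr_params, as.list(setNames(vals, keys)))
}

#' The closed set of model variant tags
#'
#' Four nonlinear models plus the six linearized counterparts.  The suffix
#' names the dynamics imposed on the parent's equilibria: \code{_LV} fully
#' proportional terms, \code{_LVV} logistic growth retained, \code{_RM}
#' logistic growth and Holling type II retained.
#'
#' @return character vector of the ten tags.
#' @export
model_variants <- function() {
  c("LV", "LVV", "RM", "RMS",
    "LVV_LV", "RM_LV", "RM_LVV", "RMS_LV", "RMS_LVV", "RMS_RM")
}

check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !(variant %in% model_variants()))
    stop("unknown model variant '", paste(variant, collapse = ","),
         "'; see model_variants()")
  variant
}

#' @rdname model_variants
#' @param variant a variant tag.
#' @export
is_linearized <- function(variant) {
  check_variant(variant)
  grepl("_", variant, fixed = TRUE)
}

#' @rdname model_variants
#' @export
parent_variant <- function(variant) {
  check_variant(variant)
  sub("_.*$", "", variant)
}

#' @rdname model_variants
#' @export
target_dynamics <- function(variant) {
  check_variant(variant)
  if (!is_linearized(variant)) stop("'", variant, "' is not linearized")
  sub("^.*_", "", variant)
}

# integer codes shared with the compiled integrator (src/rk45.cpp)
variant_code <- function(variant) {
  match(check_variant(variant), model_variants()) - 1L
}

# 12-slot parameter vector shared with the compiled integrator:
# r K g a l e m F z r_lin g_lin F_lin
pack_params <- function(variant, params) {
  if (is_linearized(variant)) {
    if (!inherits(params, "cr_linsys"))
      stop("variant '", variant, "' needs a cr_linsys (see linearize())")
    if (!identical(params$tag, variant))
      stop("cr_linsys was built for '", params$tag, "', not '", variant, "'")
    p <- params$params
    c(p$r, p$K, p$g, p$a, p$l, p$e, p$m, p$F, p$z,
      params$r_lin, params$g_lin, params$F_lin)
  } else {
    if (!inherits(params, "cr_params"))
      stop("variant '", variant, "' needs a cr_params object")
    c(params$r, params$K, params$g, params$a, params$l, params$e,
      params$m, params$F, params$z, NA_real_, NA_real_, NA_real_)
  }
}
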