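#' Nullclines of a model variant
#'
#' Returns the nontrivial resource and consumer nullclines (the loci where
#' dA/dt = 0 and dZ/dt = 0 for positive densities) as coordinate tables,
#' from the closed-form expressions of each variant.  Consumer nullclines
#' are vertical lines for every variant except RMS, whose type III loss
#' makes the nullcline a curve \code{A(Z)}.
#'
#' The default window is \code{[0, 1.2 max(A*, K)] x [0, 1.5 max(Z*)]},
#' covering the equilibria and, for oscillatory regimes, the cycles around
#' them.
#'
#' @inheritParams cr_rhs
#' @param window list with components \code{A = c(lo, hi)} and
#'   \code{Z = c(lo, hi)}; computed from the equilibria when NULL.
#' @param resolution points per curve (default 400).
#' @return object of class \code{cr_nullclines}: a list with data frames
#'   \code{resource} and \code{consumer} (columns \code{A}, \code{Z},
#'   \code{which}).
#' @examples
#' nc <- nullclines("RM", cr_params(K = 5))
#' @export
nullclines <- function(variant, params, window = NULL, resolution = 400L) {
  check_variant(variant)
  v <- pack_params(variant, params)
  r <- v[1]; K <- v[2]; g <- v[3]; a <- v[4]; l <- v[5]; e <- v[6]
  m <- v[7]; Fv <- v[8]; z <- v[9]; rl <- v[10]; gl <- v[11]; Fl <- v[12]
  if (is.null(window)) {
    eqs <- tryCatch(suppressWarnings(
      equilibria(variant, params, interior_only = TRUE)),
      error = function(e) list())
    Amax <- max(c(vapply(eqs, `[[`, numeric(1), "A_star"), K), na.rm = TRUE)
    Zmax <- max(c(vapply(eqs, `[[`, numeric(1), "Z_star"), 1), na.rm = TRUE)
    window <- list(A = c(0, 1.2 * Amax), Z = c(0, 1.5 * Zmax))
  }
  Agrid <- seq(max(window$A[1L], 1e-9), window$A[2L],
               length.out = resolution)
  Zgrid <- seq(max(window$Z[1L], 0), window$Z[2L], length.out = resolution)

  res_Z <- switch(variant,
    LV      = rep((r - l) / g, resolution),
    LVV     = (r * (1 - Agrid / K) - l) / g,
    RM      = (r * (1 - Agrid / K) - l) * (Agrid + a) / g,
    RMS     = (r * Agrid * (1 - Agrid / K) - l * Agrid + l * K) *
              (Agrid + a) / (g * Agrid),
    LVV_LV  = rep((rl - l) / g, resolution),
    RM_LV   = rep((rl - l) / gl, resolution),
    RM_LVV  = (r * (1 - Agrid / K) - l) / gl,
    RMS_LV  = (rl * Agrid - l * Agrid + l * K) / (gl * Agrid),
    RMS_LVV = (r * Agrid * (1 - Agrid / K) - l * Agrid + l * K) /
              (gl * Agrid),
    RMS_RM  = (r * Agrid * (1 - Agrid / K) - l * Agrid + l * K) *
              (Agrid + a) / (g * Agrid))
  resource <- data.frame(A = Agrid, Z = res_Z, which = "resource_nullcline")
  resource <- resource[is.finite(resource$Z) &
                         resource$Z >= window$Z[1L] &
                         resource$Z <= window$Z[2L], ]

  consumer <- if (variant %in% c("RMS", "RMS_RM")) {
    # A(Z) solving e g A/(A+a) = m + (F-type loss)/Z
    q <- if (variant == "RMS") m + Fv * Zgrid / (Zgrid^2 + z^2) else
      rep(m + Fl, resolution)
    A_of_Z <- ifelse(q < e * g, a * q / (e * g - q), NA_real_)
    data.frame(A = A_of_Z, Z = Zgrid, which = "consumer_nullcline")
  } else {
    Aeq <- switch(variant,
      LV = m / (e * g), LVV = m / (e * g),
      RM = a * m / (e * g - m),
      LVV_LV = m / (e * g),
      RM_LV = m / (e * gl), RM_LVV = m / (e * gl),
      RMS_LV = (m + Fl) / (e * gl), RMS_LVV = (m + Fl) / (e * gl))
    data.frame(A = rep(Aeq, resolution), Z = Zgrid,
               which = "consumer_nullcline")
  }
  consumer <- consumer[is.finite(consumer$A) &
                         consumer$A >= window$A[1L] &
                         consumer$A <= window$A[2L], ]
  structure(list(resource = resource, consumer = consumer,
                 window = window, variant = variant),
            class = "cr_nullclines")
}

#' Phase portrait of a model variant
#'
#' Draws the nullclines, the equilibria and (optionally) one or more
#' trajectories in the (A, Z) plane using base graphics.
#'
#' @inheritParams nullclines
#' @param inits optional list of initial states; a trajectory is integrated
#'   and drawn from each.
#' @param horizon integration time for the trajectories.
#' @param ... forwarded to \code{plot}.
#' @return the \code{cr_nullclines} object, invisibly.
#' @export
plot_phase <- function(variant, params, window = NULL, inits = NULL,
                       horizon = 500, ...) {
  nc <- nullclines(variant, params, window)
  graphics::plot(NA, xlim = nc$window$A, ylim = nc$window$Z,
                 xlab = "resource A", ylab = "consumer Z",
                 main = variant, ...)
  graphics::lines(nc$resource$A, nc$resource$Z, col = "forestgreen")
  graphics::lines(nc$consumer$A, nc$consumer$Z, col = "steelblue")
  eqs <- tryCatch(suppressWarnings(equilibria(variant, params)),
                  error = function(e) list())
  for (eq in eqs)
    graphics::points(eq$A_star, eq$Z_star,
                     pch = if (eq$interior) 19 else 1)
  for (init in inits) {
    tr <- trajectory(variant, params, init, horizon)
    graphics::lines(tr$A, tr$Z, col = "grey30")
  }
  invisible(nc)
}
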