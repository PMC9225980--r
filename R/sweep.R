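#' Specify an environmental gradient
#'
#' The two gradients of the reference analyses are eutrophication (carrying
#' capacity \code{K}, range 0-10) and top-consumer pressure (\code{F},
#' range 0-0.3); defaults follow those ranges with 1000 uniform points.
#'
#' @param parameter \code{"K"} or \code{"F"}.
#' @param lo,hi gradient range (defaults per parameter).
#' @param n_points number of grid points, >= 10.
#' @return object of class \code{cr_gradient}.
#' @export
gradient_spec <- function(parameter = c("K", "F"), lo = NULL, hi = NULL,
                          n_points = 1000L) {
  parameter <- match.arg(parameter)
  if (is.null(lo)) lo <- 0
  if (is.null(hi)) hi <- if (parameter == "K") 10 else 0.3
  n_points <- as.integer(n_points)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("gradient needs lo < hi")
  if (n_points < 10L) stop("n_points must be >= 10")
  structure(list(parameter = parameter, lo = lo, hi = hi,
                 n_points = n_points),
            class = "cr_gradient")
}

grad_values <- function(grad) seq(grad$lo, grad$hi, length.out = grad$n_points)

set_param <- function(params, name, value) {
  p <- unclass(params)
  p[[name]] <- value
  do.call(cr_params, p)
}

# feasible interior equilibria at one gradient point, sorted by A;
# returns list() on solver failure or infeasibility
interior_at <- function(variant, params) {
  eqs <- tryCatch(
    suppressWarnings(equilibria(parent_variant(variant), params,
                                interior_only = TRUE)),
    error = function(e) list())
  eqs[order(vapply(eqs, `[[`, numeric(1), "A_star"))]
}

# stability of `variant` at the parent equilibrium `eq` (re-linearizing
# there when the variant is a counterpart model)
stability_at <- function(variant, params, eq) {
  if (is_linearized(variant)) {
    lin <- linearize(parent_variant(variant), params, eq,
                     target_dynamics(variant))
    eigen_pair(cr_jacobian(variant, lin, eq))
  } else {
    eigen_pair(cr_jacobian(variant, params, eq))
  }
}

#' Sweep a model along an environmental gradient
#'
#' Computes, at every grid point, the feasible interior equilibria, the
#' eigenvalues of the (re-linearized, for counterpart models) Jacobian and
#' the dynamical regime.  Counterpart variants are re-parameterized at each
#' grid point from their parent's equilibrium there, mirroring the
#' construction of an observation-based model at every level of
#' environmental stress.  RMS carries up to three coexisting branches,
#' matched across the grid by nearest-\code{A_star} continuation (jump
#' threshold 10\% of the observed \code{A} range; a new branch id is
#' allocated where a fold creates a pair).
#'
#' Grid points where the equilibrium solver fails or no feasible interior
#' equilibrium exists produce a row of \code{NA}s (flagged absent), and the
#' sweep continues.
#'
#' @param variant any tag from \code{\link{model_variants}}.
#' @param params \code{\link{cr_params}} of the (parent) model.
#' @param grad a \code{\link{gradient_spec}}.
#' @param neutral_tol passed to \code{\link{classify_regime}}.
#' @return data frame of class \code{cr_gradient_table} with columns
#'   \code{param}, \code{branch}, \code{A_star}, \code{Z_star},
#'   \code{re_lambda}, \code{im_lambda}, \code{regime}.
#' @examples
#' tb <- sweep_gradient("LVV", cr_params(), gradient_spec("K", 0, 2, n_points = 50))
#' @export
sweep_gradient <- function(variant, params, grad, neutral_tol = 1e-9) {
  check_variant(variant)
  if (!inherits(grad, "cr_gradient")) stop("grad must be a gradient_spec()")
  vals <- grad_values(grad)
  rows <- vector("list", length(vals))
  prev <- NULL          # data.frame(branch, A) of previous grid point
  next_id <- 1L
  A_seen <- 1
  for (i in seq_along(vals)) {
    p_i <- tryCatch(set_param(params, grad$parameter, vals[i]),
                    error = function(e) NULL)
    eqs <- if (is.null(p_i)) list() else interior_at(variant, p_i)
    if (!length(eqs)) {
      rows[[i]] <- data.frame(param = vals[i], branch = NA_integer_,
                              A_star = NA_real_, Z_star = NA_real_,
                              re_lambda = NA_real_, im_lambda = NA_real_,
                              regime = NA_character_)
      prev <- NULL
      next
    }
    A_now <- vapply(eqs, `[[`, numeric(1), "A_star")
    A_seen <- max(A_seen, A_now)
    jump <- 0.1 * A_seen
    ids <- integer(length(eqs))
    taken <- integer(0)
    for (k in seq_along(eqs)) {
      if (!is.null(prev)) {
        cand <- prev[!(prev$branch %in% taken), , drop = FALSE]
      } else cand <- NULL
      if (!is.null(cand) && nrow(cand)) {
        d <- abs(cand$A - A_now[k])
        j <- which.min(d)
        if (d[j] <= jump) {
          ids[k] <- cand$branch[j]
          taken <- c(taken, ids[k])
          next
        }
      }
      ids[k] <- next_id
      next_id <- next_id + 1L
      taken <- c(taken, ids[k])
    }
    recs <- lapply(seq_along(eqs), function(k) {
      eq <- eqs[[k]]
      st <- tryCatch(stability_at(variant, p_i, eq),
                     error = function(e) NULL)
      if (is.null(st))
        data.frame(param = vals[i], branch = ids[k], A_star = eq$A_star,
                   Z_star = eq$Z_star, re_lambda = NA_real_,
                   im_lambda = NA_real_, regime = NA_character_)
      else
        data.frame(param = vals[i], branch = ids[k], A_star = eq$A_star,
                   Z_star = eq$Z_star, re_lambda = st$dominant_real,
                   im_lambda = abs(Im(st$lambda1)),
                   regime = classify_regime(st, neutral_tol))
    })
    rows[[i]] <- do.call(rbind, recs)
    prev <- data.frame(branch = ids, A = A_now)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "variant") <- variant
  attr(out, "gradient") <- grad
  class(out) <- c("cr_gradient_table", "data.frame")
  out
}

#' Write a gradient table as CSV
#'
#' @param table a \code{cr_gradient_table} (or any data frame with its
#'   columns).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gradient_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
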