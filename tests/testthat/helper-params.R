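# reference parameter set used across the tests (K and F at their analysis
# defaults; individual tests override them)
ref_params <- function(...) cr_params(...)

# random parameter sets in the neighbourhood of the reference values, with
# K and F placed where all three nonlinear parents have a feasible interior
# equilibrium most of the time
draw_params <- function() {
  f <- runif(7, 0.85, 1.15)
  cr_params(r = 0.5 * f[1], K = runif(1, 4, 12), g = 0.4 * f[2],
            a = 0.6 * f[3], l = 0.01 * f[4], e = min(0.6 * f[5], 1),
            m = 0.15 * f[6], F = runif(1, 0.02, 0.2), z = 0.5 * f[7])
}

# first feasible interior equilibrium of a nonlinear parent, or NULL
interior_eq <- function(variant, params, branch = 1L) {
  eqs <- tryCatch(
    suppressWarnings(equilibria(variant, params, interior_only = TRUE)),
    error = function(e) list())
  if (length(eqs) < branch) return(NULL)
  eqs <- eqs[order(vapply(eqs, `[[`, numeric(1), "A_star"))]
  eqs[[branch]]
}

# central finite-difference Jacobian of cr_rhs (independent oracle for the
# analytic expressions)
fd_jacobian <- function(variant, params, state, h = 1e-6) {
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    hp <- h * max(1, abs(state[j]))
    up <- state; up[j] <- up[j] + hp
    dn <- state; dn[j] <- dn[j] - hp
    J[, j] <- (cr_rhs(variant, params, up) - cr_rhs(variant, params, dn)) /
      (2 * hp)
  }
  J
}

# the six linearized variant tags with their parent/target split
lin_variants <- data.frame(
  tag = c("LVV_LV", "RM_LV", "RM_LVV", "RMS_LV", "RMS_LVV", "RMS_RM"),
  parent = c("LVV", "RM", "RM", "RMS", "RMS", "RMS"),
  target = c("LV", "LV", "LVV", "LV", "LVV", "RM"),
  stringsAsFactors = FALSE)
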