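test_that("linear coefficients match their defining expressions", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  lin <- linearize("RM", p5, eq, "LV")
  expect_equal(lin$r_lin, 0.4)     # r (1 - A*/K) with A* = 1
  expect_equal(lin$g_lin, 0.25)    # g / (A* + a)
  expect_identical(lin$retained_terms, character(0))
  # type III loss: F Z*/(Z*^2 + z^2)
  prms <- cr_params(K = 10, F = 0.1, z = 0.5)
  eqr <- interior_eq("RMS", prms)
  linr <- linearize("RMS", prms, eqr, "LV")
  expect_equal(linr$F_lin,
               prms$F * eqr$Z_star / (eqr$Z_star^2 + prms$z^2))
  # r_lin -> r as A*/K -> 0
  pbig <- cr_params(K = 1e12)
  eqb <- closed_form_equilibria("LVV", pbig)[[1]]
  linb <- linearize("LVV", pbig, eqb, "LV")
  expect_equal(linb$r_lin, pbig$r, tolerance = 1e-9)
})

test_that("linearization is refused for infeasible equilibria and bad targets", {
  p <- cr_params(K = 0.5)   # below the LVV invasion threshold
  eq <- closed_form_equilibria("LVV", p)[[1]]
  expect_error(linearize("LVV", p, eq, "LV"), "infeasible")
  p5 <- cr_params(K = 5)
  eq5 <- closed_form_equilibria("RM", p5)[[1]]
  expect_error(linearize("RM", p5, eq5, "RM"), "not strictly simpler")
  expect_error(linearize("LV", p5, eq5, "LV"), "parent must be")
})

test_that("equilibrium and flux preservation holds for all six counterparts", {
  set.seed(7)
  done <- setNames(integer(nrow(lin_variants)), lin_variants$tag)
  while (any(done < 100)) {
    p <- draw_params()
    for (i in seq_len(nrow(lin_variants))) {
      tag <- lin_variants$tag[i]
      if (done[[tag]] >= 100) next
      eq <- interior_eq(lin_variants$parent[i], p)
      if (is.null(eq)) next
      lin <- linearize(lin_variants$parent[i], p, eq, lin_variants$target[i])
      res <- preservation_residual(lin_variants$parent[i], p, lin)
      tol <- 1e-10 * max(1, eq$A_star, eq$Z_star)
      expect_lt(res[["rhs_residual"]], tol)
      expect_lt(res[["flux_mismatch"]], tol)
      done[[tag]] <- done[[tag]] + 1L
    }
  }
})

test_that("a perturbed interaction coefficient shows up as a flux mismatch", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  lin <- linearize("RM", p5, eq, "LV")
  flux <- consumption_flux("RM", p5, eq)
  expect_equal(flux, 0.39)   # g Z* A* / (A* + a) = 0.4 * 1.56 / 1.6
  lin$g_lin <- lin$g_lin * 1.01
  res <- preservation_residual("RM", p5, lin)
  expect_equal(res[["flux_mismatch"]], 0.01 * flux, tolerance = 1e-9)
})

test_that("Jacobian identities between parent and counterpart elements hold", {
  p5 <- cr_params(K = 5)
  # RM vs RM_LV: J12 equal; J21 scaled by (A*+a)/a; J22 both zero
  eq <- closed_form_equilibria("RM", p5)[[1]]
  J <- cr_jacobian("RM", p5, eq)
  lin <- linearize("RM", p5, eq, "LV")
  Jl <- cr_jacobian("RM_LV", lin, eq)
  expect_equal(Jl[1, 2], J[1, 2])
  expect_equal(Jl[2, 1], J[2, 1] * (eq$A_star + p5$a) / p5$a)
  expect_equal(Jl[2, 2], 0)
  expect_equal(J[2, 2], 0)
  expect_equal(Jl[1, 1], 0)
  # LVV vs LVV_LV: J(LV)11 = J11 + r A*/K (both sides evaluated at eq)
  eqv <- closed_form_equilibria("LVV", p5)[[1]]
  Jv <- cr_jacobian("LVV", p5, eqv)
  linv <- linearize("LVV", p5, eqv, "LV")
  Jvl <- cr_jacobian("LVV_LV", linv, eqv)
  expect_equal(Jvl[1, 1], Jv[1, 1] + p5$r * eqv$A_star / p5$K)
  expect_equal(Jvl[1, 1], 0)
  # RMS vs RMS_LV: J(lin)22 = J22 + 2FZ*z^2/(Z*^2+z^2)^2 - FZ*/(Z*^2+z^2) = 0
  pr <- cr_params(K = 10, F = 0.15)
  eqr <- interior_eq("RMS", pr)
  Jr <- cr_jacobian("RMS", pr, eqr)
  linr <- linearize("RMS", pr, eqr, "LV")
  Jrl <- cr_jacobian("RMS_LV", linr, eqr)
  Zs <- eqr$Z_star
  expect_equal(Jrl[2, 2],
               Jr[2, 2] + 2 * pr$F * Zs * pr$z^2 / (Zs^2 + pr$z^2)^2 -
                 pr$F * Zs / (Zs^2 + pr$z^2))
  expect_equal(Jrl[2, 2], 0, tolerance = 1e-12)
})

test_that("the linearized-parameter JSON report round-trips its fields", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  lin <- linearize("RM", p5, eq, "LVV")
  path <- withr::local_tempfile(fileext = ".json")
  write_linsys_json(lin, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$tag, "RM_LVV")
  expect_equal(obj$g_lin, lin$g_lin)
  expect_equal(obj$retained_terms, "logistic")
  expect_equal(obj$parent_equilibrium$A_star, eq$A_star)
})
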