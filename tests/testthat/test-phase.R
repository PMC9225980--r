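test_that("nullclines satisfy their defining equations and cross at equilibria", {
  for (spec in list(list(v = "LV", p = ref_params()),
                    list(v = "LVV", p = cr_params(K = 5)),
                    list(v = "RM", p = cr_params(K = 5)),
                    list(v = "RMS", p = cr_params(K = 10, F = 0.15)))) {
    nc <- nullclines(spec$v, spec$p)
    res <- nc$resource
    for (i in seq(1, nrow(res), length.out = 25)) {
      st <- c(res$A[i], res$Z[i])
      expect_lt(abs(cr_rhs(spec$v, spec$p, st)[1]), 1e-8 * max(1, st))
    }
    con <- nc$consumer
    for (i in seq(1, nrow(con), length.out = 25)) {
      st <- c(con$A[i], max(con$Z[i], 1e-9))
      expect_lt(abs(cr_rhs(spec$v, spec$p, st)[2]), 1e-8 * max(1, st))
    }
    # every interior equilibrium lies on both curves
    for (eq in equilibria(spec$v, spec$p, interior_only = TRUE)) {
      dres <- min(sqrt((res$A - eq$A_star)^2 + (res$Z - eq$Z_star)^2))
      expect_lt(dres, 0.05)
      rhs_eq <- cr_rhs(spec$v, spec$p, c(eq$A_star, eq$Z_star))
      expect_lt(max(abs(rhs_eq)), 1e-6)
    }
  }
})

test_that("LV consumer nullcline is the vertical line A = m/(eg)", {
  nc <- nullclines("LV", ref_params())
  expect_true(all(abs(nc$consumer$A - 0.625) < 1e-12))
})

test_that("linearized RM nullclines are straight lines through the parent equilibrium", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  lin <- linearize("RM", p5, eq, "LV")
  nc <- nullclines("RM_LV", lin)
  # resource nullcline horizontal at Z*, consumer vertical at A*
  expect_true(all(abs(nc$resource$Z - eq$Z_star) < 1e-10))
  expect_true(all(abs(nc$consumer$A - eq$A_star) < 1e-10))
})

test_that("neutral LV-dynamics orbits re-cross their section without radial drift", {
  p5 <- cr_params(K = 5)
  eqv <- closed_form_equilibria("LVV", p5)[[1]]
  lin <- linearize("LVV", p5, eqv, "LV")
  # small displacement; angular frequency ~ sqrt(det J)
  J <- cr_jacobian("LVV_LV", lin, eqv)
  period <- 2 * pi / sqrt(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  start <- c(eqv$A_star * 1.02, eqv$Z_star)
  tr <- trajectory("LVV_LV", lin, start, horizon = 11 * period,
                   dt_out = period / 400, rtol = 1e-10, atol = 1e-12)
  # crossings of the section A = A* on the upper half (Z > Z*), where the
  # counterclockwise orbit moves towards smaller A: one per revolution
  above <- tr$Z > eqv$Z_star
  crossing <- which(diff(sign(tr$A - eqv$A_star)) < 0 & above[-1])
  expect_gte(length(crossing), 10)
  z_at_cross <- tr$Z[crossing]
  drift <- abs(z_at_cross[length(z_at_cross)] - z_at_cross[1]) /
    (z_at_cross[1] - eqv$Z_star)
  expect_lt(drift, 0.001)
})

test_that("trajectories spiral as the local regime dictates", {
  p5 <- cr_params(K = 5)
  eqv <- closed_form_equilibria("LVV", p5)[[1]]
  tr <- trajectory("LVV", p5, c(eqv$A_star * 1.1, eqv$Z_star * 1.1),
                   horizon = 2000)
  n <- nrow(tr)
  d_end <- max(abs(tr$A[n] - eqv$A_star), abs(tr$Z[n] - eqv$Z_star))
  expect_lt(d_end, 1e-3)   # stable focus: inward spiral
  eqr <- closed_form_equilibria("RM", p5)[[1]]
  tr2 <- trajectory("RM", p5, c(eqr$A_star * 1.01, eqr$Z_star * 1.01),
                    horizon = 3000)
  tail_A <- tr2$A[tr2$time > 2000]
  expect_gt(diff(range(tail_A)), 0.5)   # outward onto a bounded cycle
  expect_lt(max(tr2$A), 1.2 * p5$K)
})
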