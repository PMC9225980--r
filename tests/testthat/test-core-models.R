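test_that("right-hand sides vanish at the closed-form equilibria", {
  p <- ref_params()
  # LV interior: A* = m/(eg) = 0.625, Z* = (r-l)/g = 1.225
  expect_equal(cr_rhs("LV", p, c(0.625, 1.225)), c(0, 0), tolerance = 1e-12)
  expect_equal(cr_rhs("LV", p, c(0, 0)), c(0, 0))
  # RMS at the origin keeps only the chemostat influx lK
  expect_equal(cr_rhs("RMS", p, c(0, 0)), c(p$l * p$K, 0))
  for (v in c("LV", "LVV", "RM")) {
    for (K in c(2, 5, 10)) {
      pk <- cr_params(K = K)
      for (eq in closed_form_equilibria(v, pk)) {
        if (eq$Z_star < 0) next
        res <- max(abs(cr_rhs(v, pk, c(eq$A_star, eq$Z_star))))
        expect_lt(res, 1e-10 * max(1, eq$A_star, eq$Z_star))
      }
    }
  }
})

test_that("rhs rejects bad inputs", {
  p <- ref_params()
  expect_error(cr_rhs("XX", p, c(1, 1)), "unknown model variant")
  expect_error(cr_rhs("LV", p, c(-1, 1)), "negative state")
  expect_error(cr_rhs("LVV_LV", p, c(1, 1)), "cr_linsys")
})

test_that("closed-form equilibria match hand evaluation", {
  expect_equal(closed_form_equilibria("LV", ref_params())[[1]][c("A_star", "Z_star")],
               list(A_star = 0.625, Z_star = 1.225))
  rm5 <- closed_form_equilibria("RM", cr_params(K = 5))[[1]]
  expect_equal(rm5$A_star, 1.0)
  expect_equal(rm5$Z_star, 1.56)
  # below the invasion threshold the interior consumer branch is negative
  lvv <- closed_form_equilibria("LVV", cr_params(K = 0.5))[[1]]
  expect_lt(lvv$Z_star, 0)
  expect_false(lvv$interior)
  expect_error(closed_form_equilibria("RMS", ref_params()), "no closed form")
})

test_that("RMS interior equilibrium count is 1 / 3 / 1 across the F range", {
  counts <- vapply(c(0, 0.15, 0.29), function(Fv)
    length(suppressWarnings(
      numeric_equilibria_rms(cr_params(K = 10, F = Fv)))), integer(1))
  expect_identical(counts, c(1L, 3L, 1L))
  eqs <- numeric_equilibria_rms(cr_params(F = 0.15))
  A <- vapply(eqs, `[[`, numeric(1), "A_star")
  expect_identical(A, sort(A))
  expect_identical(vapply(eqs, `[[`, integer(1), "branch_id"), 1:3)
  for (eq in eqs) {
    res <- max(abs(cr_rhs("RMS", cr_params(F = 0.15),
                          c(eq$A_star, eq$Z_star))))
    expect_lt(res, 1e-10 * max(1, eq$A_star, eq$Z_star))
  }
})

test_that("the RMS solver with influx and type III removed recovers the RM closed form", {
  p <- cr_params(K = 10, F = 0)
  eqs <- numeric_equilibria_rms(p, influx = FALSE)
  expect_length(eqs, 1L)
  rm <- closed_form_equilibria("RM", p)[[1]]
  expect_equal(eqs[[1]]$A_star, rm$A_star, tolerance = 1e-8)
  expect_equal(eqs[[1]]$Z_star, rm$Z_star, tolerance = 1e-8)
})

test_that("LV interior Jacobian: trace 0, det m(r-l), printed elements", {
  p <- ref_params()
  eq <- closed_form_equilibria("LV", p)[[1]]
  J <- cr_jacobian("LV", p, eq)
  expect_equal(J[1, 1], 0)
  expect_equal(J[2, 2], 0)
  expect_equal(J[1, 2], -p$m / p$e)          # -0.25
  expect_equal(J[2, 1], p$e * (p$r - p$l))   # 0.294
  expect_equal(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1], p$m * (p$r - p$l))
})

test_that("jacobian refuses a stale equilibrium", {
  p <- ref_params()
  expect_error(cr_jacobian("LV", p, c(1, 1)), "stale equilibrium")
})

test_that("analytic Jacobians agree with a finite-difference oracle", {
  set.seed(42)
  checked <- setNames(integer(length(model_variants())), model_variants())
  while (any(checked < 100)) {
    p <- draw_params()
    for (v in c("LV", "LVV", "RM", "RMS")) {
      eq <- interior_eq(v, p)
      if (is.null(eq)) next
      st <- c(eq$A_star, eq$Z_star)
      if (checked[[v]] < 100) {
        expect_equal(cr_jacobian(v, p, eq), fd_jacobian(v, p, st),
                     tolerance = 1e-5, ignore_attr = TRUE)
        checked[[v]] <- checked[[v]] + 1L
      }
      for (i in which(lin_variants$parent == v)) {
        tag <- lin_variants$tag[i]
        if (checked[[tag]] >= 100) next
        lin <- linearize(v, p, eq, lin_variants$target[i])
        expect_equal(cr_jacobian(tag, lin, eq), fd_jacobian(tag, lin, st),
                     tolerance = 1e-5, ignore_attr = TRUE)
        checked[[tag]] <- checked[[tag]] + 1L
      }
    }
  }
})
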