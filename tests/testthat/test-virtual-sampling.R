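test_that("noise-free observations equal the model term values", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  obs <- sample_observation("RM", p5, eq)
  expect_equal(obs$consumption_flux, 0.39)       # g Z* A*/(A*+a)
  expect_equal(obs$production_flux, p5$r * 1 * (1 - 1 / 5))
  expect_equal(obs$top_loss_flux, 0)
  eqlv <- closed_form_equilibria("LV", ref_params())[[1]]
  obslv <- sample_observation("LV", ref_params(), eqlv)
  expect_equal(obslv$consumption_flux, 0.30625)  # g Z* A*
  # deterministic at zero noise
  expect_identical(unclass(obs)[1:5],
                   unclass(sample_observation("RM", p5, eq))[1:5])
})

test_that("zero-noise fits reproduce the equilibrium-preserving linearization", {
  set.seed(11)
  for (rep in 1:25) {
    p <- draw_params()
    for (v in c("LVV", "RM", "RMS")) {
      eq <- interior_eq(v, p)
      if (is.null(eq)) next
      obs <- sample_observation(v, p, eq)
      fit <- fit_linear_from_observation(obs)
      lin <- linearize(v, p, eq, "LV")
      expect_equal(fit$r_lin, lin$r_lin, tolerance = 1e-12)
      expect_equal(fit$g_lin, lin$g_lin, tolerance = 1e-12)
      expect_equal(fit$F_lin, lin$F_lin, tolerance = 1e-12)
      res <- preservation_residual(v, p, fit)
      expect_lt(res[["rhs_residual"]], 1e-10 * max(1, eq$A_star, eq$Z_star))
    }
  }
})

test_that("noisy recovery is median-unbiased and improves as noise shrinks", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  g_true <- linearize("RM", p5, eq, "LV")$g_lin
  fits <- function(sigma) vapply(1:500, function(s) {
    obs <- sample_observation("RM", p5, eq, noise_sigma = sigma, seed = s)
    fit_linear_from_observation(obs)$g_lin
  }, numeric(1))
  g05 <- fits(0.05)
  expect_lt(abs(median(g05) - g_true) / g_true, 0.01)
  rmse <- vapply(c(0.1, 0.05, 0.01), function(sg)
    sqrt(mean((fits(sg) - g_true)^2)), numeric(1))
  expect_true(all(diff(rmse) < 0))
  # reproducible under the same seed
  o1 <- sample_observation("RM", p5, eq, noise_sigma = 0.1, seed = 99)
  o2 <- sample_observation("RM", p5, eq, noise_sigma = 0.1, seed = 99)
  expect_identical(unclass(o1)[1:5], unclass(o2)[1:5])
})

test_that("observation JSON round-trips and feeds the fitter", {
  pr <- cr_params(K = 10, F = 0.15)
  eq <- interior_eq("RMS", pr)
  obs <- sample_observation("RMS", pr, eq)
  path <- withr::local_tempfile(fileext = ".json")
  write_observation_json(obs, path)
  back <- read_observation_json(path)
  expect_equal(back$consumption_flux, obs$consumption_flux)
  fit <- fit_linear_from_observation(back)
  expect_equal(fit$tag, "RMS_LV")
  expect_equal(fit$F_lin, linearize("RMS", pr, eq, "LV")$F_lin,
               tolerance = 1e-12)
})

test_that("degenerate observations are rejected", {
  p5 <- cr_params(K = 5)
  eq <- closed_form_equilibria("RM", p5)[[1]]
  expect_error(sample_observation("RM_LV", p5, eq), "nonlinear")
  expect_error(sample_observation("RM", p5, cr_equilibrium(1, -1)),
               "interior")
  obslv <- sample_observation("LV", ref_params(),
                              closed_form_equilibria("LV", ref_params())[[1]])
  expect_error(fit_linear_from_observation(obslv), "already")
})
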