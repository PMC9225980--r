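test_that("transcritical thresholds: bisection, closed form and counterpart agree", {
  p <- ref_params()
  lvv <- detect_transcritical("LVV", p)
  expect_equal(lvv$param_value, (p$m / (p$e * p$g)) / (1 - p$l / p$r))
  lvv_lv <- detect_transcritical("LVV_LV", p, refine_tol = 1e-10)
  expect_equal(lvv_lv$param_value, lvv$param_value, tolerance = 1e-8)
  rm_ <- detect_transcritical("RM", p)
  rm_lv <- detect_transcritical("RM_LV", p, refine_tol = 1e-10)
  expect_equal(rm_lv$param_value, rm_$param_value, tolerance = 1e-8)
  rm_lvv <- detect_transcritical("RM_LVV", p, refine_tol = 1e-10)
  expect_equal(rm_lvv$param_value, rm_$param_value, tolerance = 1e-8)
  expect_error(detect_transcritical("LV", p), "not available")
  expect_error(detect_transcritical("RMS", p), "not available")
})

test_that("Hopf detection rejects variants without an oscillatory crossing", {
  p <- ref_params()
  g <- gradient_spec("K", n_points = 200)
  expect_error(detect_hopf("RM_LVV", p, g), "no Hopf")
  expect_error(detect_hopf("LVV", p, g), "no Hopf")
})

test_that("fully linear and partially linear variants produce no folds", {
  p <- ref_params()
  gF <- gradient_spec("F", n_points = 60)
  gK <- gradient_spec("K", n_points = 60)
  expect_identical(detect_fold("RMS_LV", p, gF), list())
  expect_identical(detect_fold("RMS_LVV", p, gF), list())
  expect_identical(detect_fold("RMS_RM", p, gF), list())
  expect_identical(detect_fold("RM", p, gK), list())
  expect_identical(detect_fold("LVV_LV", p, gK), list())
})

test_that("RMS branch count along F follows the 1 -> 3 -> 1 fold structure", {
  tb <- sweep_gradient("RMS", ref_params(), gradient_spec("F", n_points = 150))
  counts <- tapply(tb$branch, tb$param, function(b) sum(!is.na(b)))
  expect_identical(sort(unique(as.integer(counts))), c(1L, 3L))
  # one contiguous 3-branch window
  runs <- rle(as.integer(counts) == 3L)
  expect_identical(sum(runs$values), 1L)
  # branch 1 (oscillatory, lowest A) persists from F = 0 up to the window end
  b1 <- tb[!is.na(tb$branch) & tb$branch == 1L, ]
  expect_equal(min(b1$param), 0)
})

test_that("grid refinement does not move detected events beyond tolerance", {
  p <- ref_params()
  h1 <- detect_hopf("RM", p, gradient_spec("K", n_points = 250))
  h2 <- detect_hopf("RM", p, gradient_spec("K", n_points = 500))
  expect_lt(abs(h1$param_value - h2$param_value), 1e-6)
  t1 <- detect_transcritical("LVV_LV", p,
                             gradient_spec("K", n_points = 250))
  t2 <- detect_transcritical("LVV_LV", p,
                             gradient_spec("K", n_points = 500))
  expect_lt(abs(t1$param_value - t2$param_value), 1e-6)
})

test_that("attractor probes separate cycles from local recovery", {
  p5 <- cr_params(K = 5)
  eq5 <- closed_form_equilibria("RM", p5)[[1]]
  expect_equal(attractor_probe("RM", p5, eq5), "limit_cycle")
  p2 <- cr_params(K = 2)
  eq2 <- closed_form_equilibria("RM", p2)[[1]]
  expect_equal(attractor_probe("RM", p2, eq2), "settles_to_eq")
  # inside the homoclinic window the oscillatory branch escapes to the
  # alternative stable node
  pr <- cr_params(K = 10, F = 0.15)
  eqr <- interior_eq("RMS", pr)
  expect_equal(attractor_probe("RMS", pr, eqr), "other_attractor")
})

test_that("event JSON writer emits the event fields", {
  path <- withr::local_tempfile(fileext = ".json")
  write_events_json(list(cr_event("hopf", 2.65, 1L, 1e-6)), path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$kind, "hopf")
  expect_equal(obj$param_value, 2.65)
})
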