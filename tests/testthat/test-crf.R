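test_that("beta is ln(RR) over the increment", {
  expect_equal(beta_from_rr(1.062, 10), 0.006015392281974714,
               tolerance = 1e-15)
  expect_equal(beta_from_rr(1.083, 10), 0.007973496801885352,
               tolerance = 1e-15)
  expect_equal(beta_from_rr(1.0, 10), 0)
  expect_error(beta_from_rr(0, 10), "> 0")
  expect_error(beta_from_rr(1.05, 0), "> 0")
})

test_that("the log-linear CRF reproduces the study relative risks", {
  crf <- loglinear_crf(c(1.062, 1.040, 1.083), counterfactual = 10)
  rr <- relative_risk(crf, 35.45)
  expect_equal(unname(rr[["central"]]), exp(log(1.062) / 10 * 25.45),
               tolerance = 1e-12)
  expect_equal(unname(rr[["central"]]), 1.16543, tolerance = 1e-5)
  expect_identical(unclass(relative_risk(crf, 10)),
                   c(central = 1, low = 1, high = 1))

  st <- loglinear_crf(1.0123, counterfactual = 25)
  expect_equal(unname(relative_risk(st, 35.45)[["central"]]), 1.01286,
               tolerance = 1e-5)
})

test_that("log-linear RR is 1 below the counterfactual and monotone above", {
  crf <- loglinear_crf(c(1.062, 1.040, 1.083), counterfactual = 10)
  below <- vapply(seq(0, 10, by = 1), function(x)
    unname(relative_risk(crf, x)[["central"]]), numeric(1))
  expect_identical(below, rep(1, 11))
  grid <- vapply(seq(10, 100, by = 0.5), function(x)
    unname(relative_risk(crf, x)[["central"]]), numeric(1))
  expect_true(all(diff(grid) >= 0))
})

test_that("beta_from_rr and the CRF compose to the identity", {
  for (r in c(1.0045, 1.062, 1.3, 2)) {
    crf <- loglinear_crf(r, increment = 10, counterfactual = 5)
    expect_equal(unname(relative_risk(crf, 15)[["central"]]), r,
                 tolerance = 1e-12)
  }
})

test_that("triple ordering survives log-linear evaluation", {
  crf <- loglinear_crf(c(1.062, 1.040, 1.083), counterfactual = 10)
  for (x in c(10, 10.01, 20, 35.45, 99)) {
    rr <- relative_risk(crf, x)
    expect_true(rr[["low"]] <= rr[["central"]] &&
                  rr[["central"]] <= rr[["high"]])
  }
})

test_that("AP/RR inversion round-trips", {
  expect_equal(rr_from_ap(0.1842), 1.2258, tolerance = 1e-4)
  expect_equal(rr_from_ap(0), 1)
  expect_equal(rr_from_ap(0.5), 2)
  for (rr in seq(1, 5, by = 0.25))
    expect_equal(rr_from_ap(1 - 1 / rr), rr, tolerance = 1e-12)
  expect_error(rr_from_ap(1), "\\[0, 1\\)")
  expect_error(rr_from_ap(-0.1), "\\[0, 1\\)")
})

test_that("the IER curve has its closed-form values and limits", {
  c1 <- ier_crf("LC", alpha = 1, gamma = 0.1, delta = 1, zcf = 0)
  expect_equal(unname(relative_risk(c1, 10)[["central"]]),
               1 + (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(unname(relative_risk(c1, 10)[["central"]]), 1.6321,
               tolerance = 1e-4)
  expect_equal(unname(relative_risk(c1, 0)[["central"]]), 1)
  flat <- ier_crf("COPD", alpha = 0, gamma = 0.1, delta = 1, zcf = 5)
  expect_equal(unname(relative_risk(flat, 50)[["central"]]), 1)
})

test_that("the IER curve is continuous at zcf, monotone, and saturates", {
  crf <- ier_crf("ALRI", alpha = 0.4, gamma = 0.07, delta = 1.2, zcf = 15)
  eps <- 1e-8
  expect_equal(unname(relative_risk(crf, 15 + eps)[["central"]]), 1,
               tolerance = 1e-6)
  grid <- vapply(seq(15, 500, length.out = 400), function(z)
    unname(relative_risk(crf, z)[["central"]]), numeric(1))
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid <= 1 + 0.4 + 1e-12))
  expect_equal(grid[length(grid)], 1.4, tolerance = 1e-3)
})

test_that("fit_ier_scale hits the calibration point and is idempotent", {
  tpl <- ier_crf("LC", alpha = 1, gamma = 0.05, delta = 1, zcf = 2.4)
  fitted <- fit_ier_scale(tpl, z_obs = 35.45, rr_obs = 1.2258)
  expect_equal(unname(relative_risk(fitted, 35.45)[["central"]]), 1.2258,
               tolerance = 1e-9)
  again <- fit_ier_scale(fitted, 35.45,
                         unname(relative_risk(fitted, 35.45)[["central"]]))
  expect_equal(again$alpha, fitted$alpha, tolerance = 1e-12)

  # linearization: alpha -> eps / (1 - exp(-gamma (z - zcf)^delta))
  eps <- 1e-9
  tiny <- fit_ier_scale(tpl, 35.45, 1 + eps)
  expect_equal(tiny$alpha, eps / (1 - exp(-0.05 * (35.45 - 2.4))),
               tolerance = 1e-6)

  expect_error(fit_ier_scale(tpl, 1, 1.2), "exceed")
  expect_error(fit_ier_scale(tpl, 35.45, 1), "> 1")
  nog <- ier_crf("LC", alpha = 1, gamma = 0, delta = 1, zcf = 2.4)
  expect_error(fit_ier_scale(nog, 35.45, 1.2), "infeasible")
})

test_that("the registry round-trips through JSON and rebuilds CRFs", {
  reg <- default_crf_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_crf_registry(reg, path)
  back <- read_crf_registry(path)
  expect_equal(back, reg, tolerance = 1e-12)
  lt <- crf_from_registry(back, "total_mortality_long_term")
  expect_s3_class(lt, "loglinear_crf")
  expect_equal(unname(lt$source_rr[["central"]]), 1.062)
  lc <- crf_from_registry(back, "LC")
  expect_s3_class(lc, "ier_crf")
  # calibrated so the curve passes through the published AP at 35.45
  expect_equal(unname(relative_risk(lc, 35.45)[["central"]]),
               rr_from_ap(0.1842), tolerance = 1e-9)
  expect_error(crf_from_registry(back, "nonexistent"), "no CRF")
})
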