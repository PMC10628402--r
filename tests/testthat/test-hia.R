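test_that("attributable proportion follows AP = 1 - 1/RR on triples", {
  crf <- loglinear_crf(c(1.062, 1.040, 1.083), counterfactual = 10)
  ap <- attributable_proportion(relative_risk(crf, 35.45))
  expect_equal(round_half_up(100 * unname(ap[["central"]]), 2), 14.19)
  expect_identical(unclass(attributable_proportion(triple(1, 1, 1))),
                   c(central = 0, low = 0, high = 0))
  st <- loglinear_crf(1.0123, counterfactual = 25)
  ap_st <- attributable_proportion(relative_risk(st, 35.45))
  expect_equal(unname(ap_st[["central"]]), 0.012694, tolerance = 1e-4)
  expect_error(attributable_proportion(triple(0.9, 0.9, 0.9)), "below 1")
})

test_that("expected cases prefer observed counts over rate arithmetic", {
  lc <- expected_cases(population_group("LC", ">=25", 240825),
                       baseline_health("LC", incidence_value = 25.53))
  expect_equal(lc, 61.48, tolerance = 1e-4)
  tm <- expected_cases(
    population_group("TM", ">=30", 202999),
    baseline_health("total_mortality", observed_cases = 1966,
                    incidence_value = 968.48))
  expect_identical(tm, 1966)
  expect_equal(expected_cases(population_group("z", ">=30", 1e5),
                              baseline_health("z", incidence_value = 0)),
               0)
  expect_error(expected_cases(population_group("z", ">=30", 1e5),
                              baseline_health("z")), "neither")
  expect_warning(
    expected_cases(population_group("z", ">=30", 1e5),
                   baseline_health("z", observed_cases = 100,
                                   incidence_value = 150)),
    "disagree")
})

test_that("attributable cases round half-up to the published counts", {
  ac <- attributable_cases(triple(0.14194, 0.0950, 0.18366), 1966)
  expect_identical(unclass(ac$cases), c(central = 279, low = 187,
                                        high = 361))
  expect_true(all(ac$cases_raw <= 1966))
  lc <- attributable_cases(triple(0.1842, 0.1102, 0.2626), 61.48)
  expect_identical(unname(lc$cases[["central"]]), 11)
  zero <- attributable_cases(triple(0, 0, 0), 500)
  expect_identical(unclass(zero$cases), c(central = 0, low = 0, high = 0))
})

test_that("attributable rate scales the baseline incidence", {
  b <- baseline_health("total_mortality", incidence_value = 968.48)
  r <- attributable_rate(triple(0.14194, 0.14194, 0.14194), b)
  expect_equal(unname(r[["central"]]), 137.47, tolerance = 1e-3)
  expect_equal(unname(attributable_rate(
    triple(0.5, 0.5, 0.5),
    baseline_health("x", incidence_value = 200))[["central"]]), 100)
  expect_equal(unname(attributable_rate(
    triple(0.3, 0.3, 0.3),
    baseline_health("x", incidence_value = 0))[["central"]]), 0)
  # denominators other than 100,000 are rescaled
  expect_equal(unname(attributable_rate(
    triple(0.5, 0.5, 0.5),
    baseline_health("x", incidence_value = 2,
                    denominator = 1000))[["central"]]), 100)
})

test_that("assess reproduces the long- and short-term mortality rows", {
  lt <- hia_assess(make_scenario())
  expect_equal(round_half_up(100 * unname(lt$ap[["central"]]), 2), 14.19)
  expect_equal(round_half_up(100 * unname(lt$ap[["low"]]), 2), 9.50)
  expect_equal(round_half_up(100 * unname(lt$ap[["high"]]), 2), 18.37)
  expect_identical(unclass(lt$cases), c(central = 279, low = 187,
                                        high = 361))

  st <- hia_assess(make_scenario(rr = c(1.0123, 1.0045, 1.0201), x0 = 25,
                                 horizon = "short_term"))
  expect_equal(round_half_up(100 * unname(st$ap[["central"]]), 2), 1.27)
  expect_equal(round_half_up(100 * unname(st$ap[["low"]]), 2), 0.47)
  expect_equal(round_half_up(100 * unname(st$ap[["high"]]), 2), 2.06)
  expect_identical(unclass(st$cases), c(central = 25, low = 9, high = 40))
})

test_that("exposure at the counterfactual yields an all-zero impact", {
  est <- hia_assess(make_scenario(x = 10, x0 = 10))
  expect_identical(unclass(est$rr), c(central = 1, low = 1, high = 1))
  expect_identical(unclass(est$ap), c(central = 0, low = 0, high = 0))
  expect_identical(unclass(est$cases), c(central = 0, low = 0, high = 0))
})

test_that("assess agrees with a one-expression oracle on random scenarios", {
  set.seed(20160101)
  worst <- 0
  for (i in 1:1000) {
    beta <- runif(1, 0, 0.02)
    x <- runif(1, 0, 100)
    x0 <- runif(1, 0, 50)
    expected <- runif(1, 0, 5000)
    rr_per10 <- exp(beta * 10)
    est <- hia_assess(endpoint_scenario(
      "rand", exposure_summary(x, "PM2.5"), counterfactual = x0,
      crf = loglinear_crf(rr_per10, increment = 10, counterfactual = x0),
      group = population_group("g", ">=30", 1000),
      baseline = baseline_health("e", observed_cases = expected)))
    orc <- oracle_impact(beta, x, x0, expected)
    worst <- max(worst,
                 abs(unname(est$ap[["central"]]) - orc$ap),
                 abs(unname(est$rr[["central"]]) - orc$rr),
                 abs(unname(est$cases_raw[["central"]]) - orc$cases))
  }
  expect_lt(worst, 1e-12 * 5000)
})

test_that("impact is monotone in exposure and bounded by expected cases", {
  xs <- seq(10, 80, by = 5)
  ests <- lapply(xs, function(x) hia_assess(make_scenario(x = x)))
  aps <- vapply(ests, function(e) unname(e$ap[["central"]]), numeric(1))
  cs <- vapply(ests, function(e) unname(e$cases_raw[["central"]]),
               numeric(1))
  expect_true(all(diff(aps) >= 0))
  expect_true(all(diff(cs) >= 0))
  for (e in ests) expect_true(all(e$cases_raw <= e$expected_cases))
})

test_that("incidence-derived cases scale exactly with population", {
  base <- hia_assess(make_scenario(cases = NA_real_, incidence = 500,
                                   population = 50000))
  scaled <- hia_assess(make_scenario(cases = NA_real_, incidence = 500,
                                     population = 50000 * 7))
  expect_equal(unname(scaled$cases_raw[["central"]]),
               7 * unname(base$cases_raw[["central"]]), tolerance = 1e-12)
  expect_equal(unname(scaled$expected_cases), 7 * unname(base$expected_cases))
})

test_that("population table incidences are self-consistent", {
  expect_equal(round_half_up(1966 / 202999 * 1e5, 2), 968.48)
  expect_equal(round_half_up(336 / 54731 * 1e5, 2), 613.91)
})

test_that("build_report is deterministic and sorted by horizon/outcome", {
  fx <- agadir_fixture()
  ests <- lapply(fx$scenarios, hia_assess)
  r1 <- build_report(ests)
  r2 <- build_report(rev(ests))
  expect_equal(nrow(r1), 5)
  expect_identical(r1$exposure_horizon,
                   c(rep("Long-term", 4), "Short-term"))
  expect_identical(r1$outcome[1:2], c("Mortality", "Mortality"))
  expect_identical(r1$outcome[3:4], c("Morbidity", "Morbidity"))
  expect_identical(utils::capture.output(print(r1)),
                   utils::capture.output(print(build_report(ests))))
  expect_identical(sort(r1$cases_fmt), sort(r2$cases_fmt))
  expect_error(build_report(list()), "no impact")

  single <- build_report(hia_assess(make_scenario()))
  expect_equal(nrow(single), 1)
  expect_identical(single$cases_fmt, "279 (187-361)")
})
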