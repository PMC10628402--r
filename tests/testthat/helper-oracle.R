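# Straight-line reimplementation of the four-formula impact calculus,
# composed in one expression per quantity. Kept independent of the package
# internals on purpose: it is the oracle the pipeline is checked against.
oracle_impact <- function(beta, x, x0, expected, incidence_per_100k = NA) {
  ap <- 1 - exp(-beta * max(x - x0, 0))
  list(rr = exp(beta * max(x - x0, 0)), ap = ap, cases = expected * ap,
       rate = incidence_per_100k * ap)
}

# Table-1-shaped group spec reused by the synthetic-table tests.
agadir_groups <- function() {
  data.frame(label = c("total_mortality", "ALRI", "COPD"),
             age_band = c(">=30", "<5", ">=25"),
             population = c(202999, 54731, 240825),
             incidence_per_100k = c(968.48, 613.91, 11.63),
             stringsAsFactors = FALSE)
}

make_scenario <- function(rr = c(1.062, 1.040, 1.083), x = 35.45,
                          x0 = 10, population = 202999, cases = 1966,
                          incidence = NA_real_, horizon = "long_term") {
  endpoint_scenario(
    "test", exposure_summary(x, "PM2.5"), counterfactual = x0,
    crf = loglinear_crf(rr, counterfactual = x0),
    group = population_group("g", ">=30", population),
    baseline = baseline_health("total_mortality", observed_cases = cases,
                               incidence_value = incidence),
    horizon = horizon)
}
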