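#' Population at risk
#'
#' @param label endpoint or group label.
#' @param age_band age band as text, e.g. `">=30"`, `"<5"`.
#' @param population persons at risk (> 0).
#' @return an object of class `"population_group"`.
#' @export
population_group <- function(label, age_band, population) {
  stopifnot(is.character(label), is.character(age_band),
            is.numeric(population), length(population) == 1)
  if (population <= 0) stop("population must be > 0")
  structure(list(label = label, age_band = age_band,
                 population = as.numeric(population)),
            class = "population_group")
}

#' Baseline health of an endpoint
#'
#' Either an observed annual case/death count, an annual incidence per
#' `denominator` persons, or both. When both are present the observed
#' count takes precedence in [expected_cases()].
#'
#' @param endpoint endpoint name, e.g. `"total_mortality"`, `"LC"`,
#'   `"ALRI"`, `"COPD"`.
#' @param observed_cases observed annual cases or deaths (or `NA`).
#' @param incidence_value annual incidence per `denominator` persons
#'   (or `NA`).
#' @param denominator incidence denominator, persons (default 100,000).
#' @return an object of class `"baseline_health"`.
#' @export
baseline_health <- function(endpoint, observed_cases = NA_real_,
                            incidence_value = NA_real_,
                            denominator = 1e5) {
  stopifnot(is.character(endpoint), length(endpoint) == 1)
  if (!is.na(incidence_value) && incidence_value < 0)
    stop("incidence must be >= 0")
  if (!is.na(observed_cases) && observed_cases < 0)
    stop("observed cases must be >= 0")
  if (denominator <= 0) stop("denominator must be > 0")
  structure(list(endpoint = endpoint,
                 observed_cases = as.numeric(observed_cases),
                 incidence_value = as.numeric(incidence_value),
                 denominator = as.numeric(denominator)),
            class = "baseline_health")
}

#' Bind an endpoint, its population and a CRF into a scenario
#'
#' One assessable unit: an exposed population, a baseline health burden, a
#' concentration-response function and a counterfactual concentration.
#'
#' @param label scenario label (one report row).
#' @param exposure an [exposure_summary()].
#' @param counterfactual counterfactual concentration, µg/m³ (>= 0).
#' @param crf a [loglinear_crf()] or [ier_crf()].
#' @param group a [population_group()].
#' @param baseline a [baseline_health()].
#' @param horizon `"long_term"` or `"short_term"`.
#' @param outcome `"Mortality"` or `"Morbidity"` (report grouping).
#' @param ap_override optional attributable-proportion [triple()]
#'   (fractions, not percent). When supplied, the CRF is bypassed and the
#'   stated AP drives the case arithmetic — the route to reproduce
#'   published tables whose CRF parameters are not public.
#' @param concentration concentration at which the CRF is evaluated;
#'   defaults to `exposure$annual_mean`. Supply a rounded value to
#'   reproduce analyses that were keyed in at reporting precision.
#' @return an object of class `"endpoint_scenario"`.
#' @export
endpoint_scenario <- function(label, exposure, counterfactual, crf, group,
                              baseline,
                              horizon = c("long_term", "short_term"),
                              outcome = c("Mortality", "Morbidity"),
                              ap_override = NULL, concentration = NULL) {
  horizon <- match.arg(horizon)
  outcome <- match.arg(outcome)
  stopifnot(inherits(exposure, "exposure_summary"),
            inherits(group, "population_group"),
            inherits(baseline, "baseline_health"))
  if (!inherits(crf, "crf")) stop("crf must be a loglinear_crf or ier_crf")
  if (counterfactual < 0) stop("counterfactual must be >= 0")
  if (is.null(concentration)) concentration <- exposure$annual_mean
  if (!is.null(ap_override)) ap_override <- as_triple(ap_override)
  structure(list(label = label, exposure = exposure,
                 concentration = as.numeric(concentration),
                 counterfactual = as.numeric(counterfactual), crf = crf,
                 group = group, baseline = baseline, horizon = horizon,
                 outcome = outcome, ap_override = ap_override),
            class = "endpoint_scenario")
}

#' Attributable proportion from relative risk
#'
#' AP = 1 - 1/RR: the fraction of the baseline burden attributable to
#' exposure above the counterfactual. Applied componentwise to a
#' central/low/high RR triple; ordering is preserved because the map is
#' monotone. RR below 1 is rejected — the hard counterfactual threshold
#' means negative attribution never arises.
#'
#' @param rr a [triple()] of relative risks (each >= 1), or a single RR.
#' @return a [triple()] of proportions in \[0, 1).
#' @export
#' @examples
#' attributable_proportion(triple(1.16543, 1.10497, 1.22498))
attributable_proportion <- function(rr) {
  rr <- as_triple(rr)
  if (any(rr < 1))
    stop("relative risk below 1: attributable proportion undefined ",
         "(negative attribution is disallowed)")
  triple(1 - 1 / rr[["central"]], 1 - 1 / rr[["low"]],
         1 - 1 / rr[["high"]])
}

#' Expected annual cases of an endpoint
#'
#' The baseline burden B entering BE = B x AP and NE = N x AP. An observed
#' count, when present, takes precedence over a rate reconstruction
#' (population x incidence / denominator); if both are present and
#' disagree by more than 1%, a warning flags the inconsistency.
#'
#' @param group a [population_group()].
#' @param baseline a [baseline_health()].
#' @return expected events per year (numeric scalar).
#' @export
#' @examples
#' g <- population_group("LC", ">=25", 240825)
#' b <- baseline_health("LC", incidence_value = 25.53)
#' expected_cases(g, b) # 61.48
expected_cases <- function(group, baseline) {
  stopifnot(inherits(group, "population_group"),
            inherits(baseline, "baseline_health"))
  from_rate <- if (!is.na(baseline$incidence_value))
    group$population * baseline$incidence_value / baseline$denominator
  else NA_real_
  if (!is.na(baseline$observed_cases)) {
    if (!is.na(from_rate) && baseline$observed_cases > 0 &&
        abs(from_rate - baseline$observed_cases) >
          0.01 * baseline$observed_cases)
      warning(sprintf(
        "observed cases (%s) and incidence-derived cases (%.2f) disagree by >1%%; using observed",
        format(baseline$observed_cases), from_rate), call. = FALSE)
    return(baseline$observed_cases)
  }
  if (is.na(from_rate))
    stop("baseline provides neither observed cases nor an incidence")
  from_rate
}

#' Attributable case counts
#'
#' NE = N x AP applied to the expected annual burden: the cases
#' theoretically avoidable were exposure at the counterfactual. Counts are
#' reported as integers by rounding half-up independently on the central
#' estimate and both CI bounds; the unrounded values are retained for
#' downstream arithmetic.
#'
#' @param ap attributable-proportion [triple()] (fractions).
#' @param expected expected events per year (>= 0).
#' @return a list with `cases` (integer triple, half-up) and `cases_raw`
#'   (unrounded triple).
#' @export
#' @examples
#' attributable_cases(triple(0.14194, 0.0950, 0.18366), 1966)$cases
attributable_cases <- function(ap, expected) {
  ap <- as_triple(ap)
  stopifnot(is.numeric(expected), length(expected) == 1, expected >= 0)
  raw <- triple(ap[["central"]] * expected, ap[["low"]] * expected,
                ap[["high"]] * expected)
  rounded <- triple(round_half_up(raw[["central"]]),
                    round_half_up(raw[["low"]]),
                    round_half_up(raw[["high"]]))
  list(cases = rounded, cases_raw = raw)
}

#' Attributable rate per 100,000
#'
#' BE = B x AP with the baseline incidence B expressed per 100,000 persons
#' (rescaled if the baseline uses a different denominator).
#'
#' @param ap attributable-proportion [triple()].
#' @param baseline a [baseline_health()] carrying an incidence.
#' @return rate [triple()] per 100,000 persons per year.
#' @export
attributable_rate <- function(ap, baseline) {
  ap <- as_triple(ap)
  stopifnot(inherits(baseline, "baseline_health"))
  if (is.na(baseline$incidence_value))
    stop("baseline carries no incidence; attributable rate undefined")
  b <- baseline$incidence_value / baseline$denominator * 1e5
  triple(b * ap[["central"]], b * ap[["low"]], b * ap[["high"]])
}

#' Assess one endpoint scenario
#'
#' The full impact pipeline for one report row: evaluate the CRF at the
#' scenario concentration against its counterfactual (or take the
#' scenario's stated AP), derive the attributable proportion, and scale it
#' into attributable cases and an attributable rate per 100,000.
#'
#' @param scenario an [endpoint_scenario()].
#' @return an object of class `"impact_estimate"` with fields `rr`, `ap`,
#'   `expected_cases`, `cases` (reported integers), `cases_raw`,
#'   `rate_per_100k`, plus the scenario's labels.
#' @export
#' @examples
#' sc <- endpoint_scenario(
#'   "Total mortality",
#'   exposure_summary(35.45, "PM2.5", derivation = "converted",
#'                    conversion_factor = 0.62),
#'   counterfactual = 10,
#'   crf = loglinear_crf(c(1.062, 1.040, 1.083)),
#'   group = population_group("total_mortality", ">=30", 202999),
#'   baseline = baseline_health("total_mortality", observed_cases = 1966,
#'                              incidence_value = 968.48))
#' hia_assess(sc)
hia_assess <- function(scenario) {
  if (!inherits(scenario, "endpoint_scenario"))
    stop("expected an endpoint_scenario")
  if (!is.null(scenario$ap_override)) {
    ap <- scenario$ap_override
    rr <- triple(rr_from_ap(ap[["central"]]), rr_from_ap(ap[["low"]]),
                 rr_from_ap(ap[["high"]]))
  } else {
    rr <- relative_risk(scenario$crf, scenario$concentration,
                        x0 = scenario$counterfactual)
    ap <- attributable_proportion(rr)
  }
  expected <- expected_cases(scenario$group, scenario$baseline)
  ac <- attributable_cases(ap, expected)
  rate <- if (!is.na(scenario$baseline$incidence_value))
    attributable_rate(ap, scenario$baseline)
  else triple(NA_real_, NA_real_, NA_real_)
  structure(list(label = scenario$label, horizon = scenario$horizon,
                 outcome = scenario$outcome,
                 endpoint = scenario$baseline$endpoint,
                 age_band = scenario$group$age_band,
                 concentration = scenario$concentration,
                 counterfactual = scenario$counterfactual,
                 rr = rr, ap = ap, expected_cases = expected,
                 cases = ac$cases, cases_raw = ac$cases_raw,
                 rate_per_100k = rate),
            class = "impact_estimate")
}

fmt_ci <- function(tr, digits = 2) {
  paste0(fmt_hu(tr[["central"]], digits), " (", fmt_hu(tr[["low"]], digits),
         "-", fmt_hu(tr[["high"]], digits), ")")
}

fmt_ci_int <- function(tr) {
  paste0(round_half_up(tr[["central"]]), " (", round_half_up(tr[["low"]]),
         "-", round_half_up(tr[["high"]]), ")")
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat("Impact estimate: ", x$label, " (", sub("_", "-", x$horizon),
      ", ages ", x$age_band, ")\n", sep = "")
  cat("  exposure ", fmt_hu(x$concentration, 2), " vs counterfactual ",
      fmt_hu(x$counterfactual, 2), " µg/m³\n", sep = "")
  cat("  RR           ", fmt_ci(x$rr), "\n", sep = "")
  cat("  AP (%)       ", fmt_ci(100 * x$ap), "\n", sep = "")
  cat("  cases        ", fmt_ci_int(x$cases_raw), " of ",
      fmt_hu(x$expected_cases, 2), " expected\n", sep = "")
  if (!is.na(x$rate_per_100k[["central"]]))
    cat("  per 100,000  ", fmt_ci(x$rate_per_100k), "\n", sep = "")
  invisible(x)
}

#' @export
summary.impact_estimate <- function(object, ...) {
  out <- data.frame(
    label = object$label, horizon = object$horizon,
    endpoint = object$endpoint,
    rr = object$rr[["central"]], ap_pct = 100 * object$ap[["central"]],
    cases = round_half_up(object$cases_raw[["central"]]),
    expected = object$expected_cases)
  class(out) <- c("summary.impact_estimate", "data.frame")
  out
}

#' Assemble impact estimates into a report table
#'
#' One row per scenario with RR, AP (%) and attributable cases, each
#' formatted as `central (low-high)` at reporting precision (RR and AP to
#' 2 dp, cases as integers, all half-up). Rows are sorted stably by
#' (horizon, outcome) — long-term before short-term, mortality before
#' morbidity — so repeated runs render byte-identically.
#'
#' @param estimates a non-empty list of `"impact_estimate"` objects (or a
#'   single estimate).
#' @return a data frame of class `"hia_report"` carrying both numeric
#'   columns (unrounded) and formatted display columns.
#' @export
build_report <- function(estimates) {
  if (inherits(estimates, "impact_estimate")) estimates <- list(estimates)
  if (!is.list(estimates) || length(estimates) == 0)
    stop("no impact estimates to report")
  if (!all(vapply(estimates, inherits, TRUE, "impact_estimate")))
    stop("all elements must be impact_estimate objects")
  rows <- lapply(estimates, function(e) {
    data.frame(
      exposure_horizon = ifelse(e$horizon == "long_term", "Long-term",
                                "Short-term"),
      outcome = e$outcome, endpoint = e$endpoint, age = e$age_band,
      rr = e$rr[["central"]], rr_low = e$rr[["low"]],
      rr_high = e$rr[["high"]],
      ap_pct = 100 * e$ap[["central"]], ap_pct_low = 100 * e$ap[["low"]],
      ap_pct_high = 100 * e$ap[["high"]],
      cases = e$cases_raw[["central"]], cases_low = e$cases_raw[["low"]],
      cases_high = e$cases_raw[["high"]],
      expected_cases = e$expected_cases,
      rr_fmt = fmt_ci(e$rr), ap_fmt = fmt_ci(100 * e$ap),
      cases_fmt = fmt_ci_int(e$cases_raw),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(match(tab$exposure_horizon, c("Long-term", "Short-term")),
               match(tab$outcome, c("Mortality", "Morbidity")))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("hia_report", "data.frame")
  tab
}

#' @export
print.hia_report <- function(x, ...) {
  disp <- data.frame(Exposure = x$exposure_horizon, Outcome = x$outcome,
                     Endpoint = x$endpoint, Age = x$age,
                     `RR (95% CI)` = x$rr_fmt, `AP % (95% CI)` = x$ap_fmt,
                     `Cases (95% CI)` = x$cases_fmt,
                     check.names = FALSE, stringsAsFactors = FALSE)
  print.data.frame(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}
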