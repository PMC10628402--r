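---
title: "Attributable-fraction methods for particulate air pollution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable-fraction methods for particulate air pollution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airhia)
```

## The model

airhia implements the attributable-fraction calculus standard in
air-pollution health impact assessment (the calculus behind tools such as
WHO's AirQ+). For an annual-mean exposure $X$ (µg/m³) and a counterfactual
concentration $X_0$ below which no excess risk is attributed:

* **Log-linear CRF.** $RR(X) = \exp\{\beta (X - X_0)\}$ for $X > X_0$ and
  $RR = 1$ otherwise, with $\beta = \ln(RR_\Delta)/\Delta$ derived from a
  study relative risk $RR_\Delta$ per increment $\Delta$ (typically
  10 µg/m³).
* **IER curve.** For cause-specific endpoints (lung cancer, ALRI, COPD,
  IHD, stroke) the integrated exposure–response family
  $RR(z) = 1 + \alpha\,(1 - e^{-\gamma (z - z_{cf})^{\delta}})$ for
  $z > z_{cf}$, a saturating curve pooling ambient, household-fuel and
  smoking evidence; it is continuous at $z_{cf}$, monotone above it and
  bounded by $1 + \alpha$.
* **Attribution.** $AP = 1 - 1/RR$, attributable cases $NE = N \times AP$
  applied to the expected baseline burden, and the attributable rate
  $BE = B \times AP$ with $B$ the baseline incidence per 100,000.

Uncertainty is carried as a central/low/high triple and propagated by
evaluating the whole pipeline at the relative-risk confidence bounds, not
by the delta method. This is exact for these monotone transformations and
is what reproduces published CI bounds such as an AP interval of
(9.50, 18.37)% from an RR interval of (1.040, 1.083) per 10 µg/m³.

Key assumptions inherited from this calculus: a hard counterfactual
threshold (no negative attribution below $X_0$), a single pollutant acting
alone, and a baseline burden measured in the same population and year as
the exposure.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| conversion factor PM2.5/PM10 | — | 0.62 | WHO country factor for settings without PM2.5 monitors |
| annual guideline PM2.5 | µg/m³ | 10 | 2005 WHO AQG; long-term counterfactual |
| 24-h guideline PM2.5 | µg/m³ | 25 | 2005 WHO AQG; short-term counterfactual |
| annual guideline PM10 | µg/m³ | 20 | 2005 WHO AQG; exceedance reporting |
| IER $z_{cf}$ (LC) | µg/m³ | 2.4 | lower edge of the GBD 2015 counterfactual range |
| IER $z_{cf}$ (ALRI, COPD) | µg/m³ | 15 | WHO interim target 3 |
| RR all-cause, long-term | per 10 µg/m³ | 1.062 (1.040–1.083) | cohort-based default for adult all-cause mortality |
| RR all-cause, short-term | per 10 µg/m³ | 1.0123 (1.0045–1.0201) | time-series default |

## Display conventions and numerics

All reporting uses **round-half-up** at 2 decimal places (ratios,
percentages) or to integers (case counts), while every internal
computation propagates unrounded values. Two consequences worth knowing:

* Published exceedance ratios and CI bounds are sometimes computed from an
  already-rounded mean: 57.17 × 0.62 = 35.4454 reports as 35.45, and
  35.45/10 gives the published 3.55 where 35.4454/10 would give 3.54.
  `exceedance_ratio()` therefore returns both the unrounded and the
  reported value, and the packaged fixture evaluates its CRFs at 35.45 —
  the 2-dp value the original assessment was keyed in at, which is also
  the only value reproducing its upper AP bound 18.37 (the full-precision
  35.4454 gives 18.36). The full-precision conversion is retained on the
  exposure summary.
* A displayed RR can disagree with a displayed AP derived from it: the
  fixture's long-term RR evaluates to 1.1654 (displays as 1.17 under
  half-up) while assessments that truncate print 1.16. airhia never
  matches displayed RRs by truncation; counts and APs anchor on the
  unrounded RR, which is what makes 279/1,966 = 14.19% come out
  consistently.

Case counts round half-up independently on the central estimate and both
bounds; this is the unique convention consistent with the packaged
fixture's published counts (278.97 → 279, 186.76 → 187, 361.08 → 361,
24.96 → 25, 40.46 → 40, 4.39 → 4, 11.33 → 11).

When a baseline provides both an observed count and an incidence, the
observed count wins (registry counts beat rate reconstructions) and a
warning flags disagreement above 1%. Degenerate inputs are handled
explicitly: exposure at or below the counterfactual yields an identically
zero impact; RR < 1 is rejected rather than allowed to produce negative
attribution.

## Design choices made where the design was open

* **IER parameters.** The GBD parameter sets behind published
  cause-specific assessments are not printed alongside their results. The
  registry therefore ships IER curves with $\gamma = 0.05$, $\delta = 1$
  and $\alpha$ calibrated by `fit_ier_scale()` so each curve passes
  through the RR implied by the published attributable proportion at the
  study exposure ($RR = 1/(1-AP)$). The curves are correct at the one
  point that matters for reproduction and plausibly shaped elsewhere;
  they are *not* the GBD curves. For reproducing published tables the
  fixture additionally carries the published AP triples as `ap_override`,
  which bypasses the CRF entirely — the route recommended whenever a
  source prints AP but not curve parameters.
* **β bounds from RR bounds.** Slope triples are always derived from the
  RR triple, $\beta = \ln(RR)/\Delta$ componentwise. (Published β
  footnotes occasionally repeat the central value as the lower bound;
  deriving from the RR CI is the self-consistent choice and reproduces
  the AP interval.)
* **Short-term assessment on the annual mean.** The short-term scenario
  evaluates the annual mean against the 24-h guideline (25 µg/m³), as
  guidance-level practice does. This is an approximation — a day-by-day
  assessment over a `daily_series` would be the principled extension —
  and the resulting short-term estimate is largely contained in the
  long-term one.
* **Pooling across stations** is caller responsibility: the exposure
  summary takes the mean as given and records `n_days` so that users can
  judge completeness (a warning fires below 75% of a year).

## The synthetic generator

`simulate_series()` emulates a single mobile monitoring station: day $t$
is $\max(0,\; m + s_t + \varepsilon_t)$ with an annual sinusoid $s_t$ of
amplitude $A$ (phase drawn once from the seed) and i.i.d. Gaussian noise
$\varepsilon_t \sim N(0, \sigma)$. Defaults ($m = 57.17$, $A = 10$,
$\sigma = 8$, 365 days) mirror the monitoring conditions of the packaged
assessment: a PM10 record with annual mean ≈ 57 µg/m³ and moderate
seasonality. The sinusoid is mean-centred over the simulated window so
that partial-year records (mobile stations rarely run a full year) remain
unbiased for the target mean; on a full 365-day year this coincides with
the uncentred form. Under these defaults the mean obeys the standard-error
bound $|\bar{x} - m| \le 3\sigma/\sqrt{n}$; truncation at zero is
negligible, and specs where it would touch more than 1% of days trigger a
warning because truncation biases the mean upward.

`simulate_health_table()` draws observed cases
Binomial(population, incidence/100,000) per group and recomputes the
incidence column from the drawn counts, as registry tables do. All
generators are pure functions of their spec: Mersenne-Twister with
inversion sampling, mandatory seeds, no global RNG state touched.

What the generator does **not** emulate: autocorrelated (synoptic)
weather-driven noise, multi-site spatial structure, instrument error and
calibration drift, and seasonality in baseline health. Passing tests on
synthetic data therefore demonstrate the correctness of the calculus and
the pipeline's statistical behaviour under idealized sampling — not the
representativity of any real monitoring record.

## Problem sizes used in validation

The test suite validates the pipeline against a straight-line
one-expression reimplementation of the four formulas on 1,000 random
scenarios (agreement to 1e-12), checks inversion round-trips and
monotonicity on dense grids, and runs a 200-replicate parameter-recovery
study at the fixture's population sizes (attributable proportion recovered
to within 0.5 percentage points in mean absolute error). These sizes give
sub-minute runtimes while leaving Monte-Carlo error well below the
tolerances checked.

## Worked example

```{r example}
fx <- agadir_fixture()
report <- build_report(lapply(fx$scenarios, hia_assess))
print(report)
```

## Known limitations

* Single-pollutant attribution only; no joint or interacting exposures.
* No life-years-lost or age-stratified life-table outputs.
* IER shapes away from the calibration point are conventions, not GBD
  estimates.
* The hard counterfactual threshold makes results insensitive to exposure
  contrasts entirely below the guideline.
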