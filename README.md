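# airhia

Health impact assessment of ambient particulate air pollution: the
attributable-fraction calculus used in burden-of-disease practice (and in
WHO's AirQ+ tool), packaged as tested, reusable R functions.

## Who it is for

Environmental epidemiologists and public-health analysts who have an
annual-mean (or daily) PM measurement, a population-at-risk table with
baseline mortality/morbidity, and published relative risks — and who want
attributable proportions, attributable case counts and rates, with
confidence intervals, against counterfactual exposure levels such as the
WHO air quality guidelines.

## The model

For exposure `X` (µg/m³) above a counterfactual `X0`:

- log-linear concentration–response: `RR(X) = exp(β (X − X0))`, with
  `β = ln(RR_Δ)/Δ` from a study relative risk per increment Δ (usually
  10 µg/m³); `RR = 1` at or below `X0`;
- integrated exposure–response (IER) for cause-specific endpoints:
  `RR(z) = 1 + α (1 − exp(−γ (z − zcf)^δ))` above `zcf`, saturating at
  `1 + α`;
- attributable proportion `AP = 1 − 1/RR`; attributable cases
  `NE = N × AP` on the expected baseline burden; attributable rate
  `BE = B × AP` per 100,000.

95% CIs are propagated by evaluating the whole pipeline at the
relative-risk bounds. PM10-only records are converted to PM2.5 by a scalar
WHO factor (0.62 by default). Reported numbers round half-up (2 dp for
ratios and percentages, integers for counts); internal arithmetic is
unrounded throughout.

## Worked example

The packaged `agadir_fixture()` is a complete urban assessment for
Agadir, Morocco, 2016: a measured PM10 annual mean of 57.17 µg/m³
(2.86 times the 2005 WHO annual PM10 guideline of 20 µg/m³), converted to
PM2.5 as 57.17 × 0.62 → 35.45 µg/m³, bound to five endpoint scenarios
(long-term all-cause mortality, lung-cancer mortality, ALRI and COPD
morbidity, short-term all-cause mortality).

```r
library(airhia)
fx <- agadir_fixture()
report <- build_report(lapply(fx$scenarios, hia_assess))
print(report)
```

```
 Exposure   Outcome   Endpoint        Age  RR (95% CI)      AP % (95% CI)      
 Long-term  Mortality total_mortality >=30 1.17 (1.10-1.22) 14.19 (9.50-18.37) 
 Long-term  Mortality LC              >=25 1.23 (1.12-1.36) 18.42 (11.02-26.26)
 Long-term  Morbidity ALRI            <5   1.17 (1.10-1.24) 14.36 (8.78-19.33) 
 Long-term  Morbidity COPD            >=25 1.19 (1.11-1.31) 15.68 (9.66-23.38) 
 Short-term Mortality total_mortality >=30 1.01 (1.00-1.02) 1.27 (0.47-2.06)   
 Cases (95% CI)
 279 (187-361) 
 11 (7-16)     
 48 (30-65)    
 4 (3-7)       
 25 (9-40)     
```

Reading the first row: with an annual PM2.5 mean of 35.45 µg/m³ and the
all-cause RR of 1.062 (1.040–1.083) per 10 µg/m³, the relative risk versus
the 10 µg/m³ guideline is 1.17 (unrounded 1.1654), 14.19% (9.50–18.37) of
the baseline burden is attributable to exposure above the guideline, and
279 (187–361) of the 1,966 observed deaths would in principle be avoidable
at guideline-level air. A single estimate prints with its rate per
100,000:

```
Impact estimate: Total mortality (long-term) (long-term, ages >=30)
  exposure 35.45 vs counterfactual 10.00 µg/m³
  RR           1.17 (1.10-1.22)
  AP (%)       14.19 (9.50-18.37)
  cases        279 (187-361) of 1966.00 expected
  per 100,000  137.47 (92.00-177.87)
```

(The ALRI row's count follows from its own AP and baseline — published
sources for this assessment print an internally inconsistent count there;
see the methods vignette.)

The same run is available from a shell:

```sh
Rscript inst/scripts/airhia fixture --out /tmp/agadir
Rscript inst/scripts/airhia assess --config /tmp/agadir/scenario.json --out /tmp/agadir/rep
Rscript inst/scripts/airhia convert --mean 57.17 --factor 0.62   # prints 35.45
Rscript inst/scripts/airhia simulate --seed 9 --out /tmp/sim     # synthetic bundle
```

Scenario bundles are plain files: `population.csv`
(label, age_band, population, cases, incidence, denominator),
`scenario.json` (exposure, counterfactual, CRF reference, horizon, and
optionally a stated AP triple) and `crf_registry.json` (editable
endpoint → CRF map). `simulate_series()` / `simulate_health_table()`
generate synthetic daily series and registry tables with mandatory seeds
and byte-reproducible output.

## Scope

No life-years-lost outputs, no multi-pollutant joint effects, no
spatial averaging/kriging across stations, no GUI. The methods vignette
(`vignettes/particulate-hia-methods.Rmd`) documents the model,
conventions (rounding, CI propagation, IER calibration) and limitations.
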