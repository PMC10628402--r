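Package: airhia
Title: Health Impact Assessment of Ambient Particulate Air Pollution
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies mortality and morbidity attributable to ambient
    fine-particle (PM2.5) exposure with the attributable-fraction calculus
    used in burden-of-disease practice: log-linear and integrated
    exposure-response (IER) concentration-response functions, attributable
    proportions via AP = 1 - 1/RR, attributable case counts and rates with
    confidence intervals propagated through the relative-risk bounds, PM10
    to PM2.5 conversion, and counterfactual scenarios against WHO air
    quality guideline levels. Includes a synthetic generator for daily
    concentration series and population/baseline-health tables, file-based
    scenario bundles, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
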