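Package: oceantoe
Title: Time of Emergence of Climate-Change Signals in Marine Ecosystem Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects when climate-change trends in drivers of marine ecosystem
    stress (sea-surface temperature, surface pH, primary production and
    thermocline oxygen) emerge from the background of natural seasonal
    variability. Implements annual-extrema preprocessing of monthly gridded
    model output, linear-trend fitting with first-order autoregressive errors
    by exact maximum likelihood, a cumulative-sum detector for the start of the
    forced signal, a two-standard-deviation emergence criterion against
    control-run variability, multi-model ensemble medians, multi-driver
    classification and area-weighted ocean-fraction curves. Ships a synthetic
    Earth-system-model generator with closed-form ground-truth emergence so the
    whole pipeline is verifiable without a model archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    lmtest,
    nortest,
    withr,
    yaml
Config/testthat/edition: 3
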