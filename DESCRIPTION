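Package: no2burden
Title: Source-Resolved Disease Burden Attributable to Nitrogen Dioxide Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative risk assessment of the disease burden attributable
    to nitrogen dioxide (NO2) from ambient air, household gas cooking, and
    secondhand smoke in urban populations. Implements capped log-linear
    concentration-response functions, population attributable and potential
    impact fractions with source apportionment, DALY estimation and human
    capital monetization, counterfactual control scenarios (source removal
    and WHO ambient targets), and a two-stage Monte Carlo engine separating
    intra-population exposure variability from concentration-response and
    baseline-rate uncertainty. Ships a calibrated synthetic cohort generator
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
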