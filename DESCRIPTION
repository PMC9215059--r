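Package: pifcost
Title: Potential Impact Fractions and Cancer Costs Attributable to Excess Body Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative risk assessment macrosimulation for the direct
    healthcare costs of cancer attributable to excess body weight (BMI >= 25
    kg/m^2). Rescales dose-response relative risks between BMI increments,
    expands them over categorical BMI strata, constructs counterfactual BMI
    distributions (historical rollback, prevalence freeze, elimination of
    obesity classes II-III, population mean shift), projects annual cost
    series by linear regression with purchasing-power-parity conversion, and
    computes potential impact fractions and attributable costs with Monte
    Carlo uncertainty intervals. Includes a synthetic-data module that
    emulates survey prevalence tables, relative-risk tables, and cost
    registries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    metafor,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
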