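Package: ssndtrisk
Title: U-Shaped Injury-Risk Modelling and Risk Zones for the Sit-to-Stand
    Navicular Drop Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the relationship between sit-to-stand navicular drop
    (SSNDT, mm) and lower-limb injury as a continuous U-shaped risk
    gradient, using random-intercept logistic regression (adaptive
    Gauss-Hermite quadrature) on clustered foot-level data. Translates the
    fitted quadratic logit into a minimum-risk point, two-sided
    odds-ratio-anchored thresholds, interpretive risk zones and screening
    metrics; quantifies threshold distinguishability with a
    participant-level bootstrap; checks for discrete risk transitions with
    segmented (breakpoint) logistic regression; and assesses measurement
    reliability with ICC(3,1). Includes a calibrated synthetic-data
    generator for clustered binary outcomes and a Monte Carlo scenario
    harness for sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
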