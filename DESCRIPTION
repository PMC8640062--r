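Package: pmburden
Title: Health Burden and Economic Valuation of Ambient PM2.5 Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: City-level health-impact-assessment chain for ambient fine
    particulate matter (PM2.5). Screens and completes daily monitoring data
    (completeness rule, PM10 regression/ratio gap filling), evaluates the
    Global Exposure Mortality Model (GEMM) relative-risk function with a
    2.4 ug/m3 counterfactual, builds adult (age > 25) cause-specific
    baseline mortality from registry-style inputs, converts relative risks
    into attributable premature deaths with confidence bounds, values them
    with a benefit-transferred Value of Statistical Life, and projects
    policy-reduction scenarios with frozen incidence rates. Ships a
    seedable synthetic-data generator emulating the 31 Indian million-plus
    non-attainment cities so the whole chain is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
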