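Package: firehia
Title: Health Impact Assessment of Wildfire Smoke PM2.5 with Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates hospital admissions attributable to fire-originated
    fine particulate matter (PM2.5) from gridded daily total-PM2.5 surfaces.
    Isolates the fire-originated component by either a chemical-transport-model
    ratio (zero-out) method or subtraction of a non-fire baseline surface,
    applies a log-linear health impact function with wildfire-specific or
    ambient concentration-response functions, and propagates uncertainty from
    both the exposure surface and the concentration-response function by Monte
    Carlo simulation, including decomposition of the confidence-interval width
    by uncertainty source. Ships a synthetic-scenario generator (drifting
    Gaussian smoke plumes, method-specific exposure error, county rates,
    clustered population) so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
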