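Package: occuInterview
Title: Single-Season Occupancy Modelling from Key-Informant Interview Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating large-mammal occupancy from key-informant
    (pastoralist) interview surveys on a grid of sites. Converts raw interview
    responses into three-state detection histories (non-detection, uncertain
    detection, certain detection) via an identification flowchart, collapses
    them conservatively to binary data, engineers grid-level habitat and
    livestock-biomass covariates, fits single-season single-species occupancy
    models (and a diagnostic multi-state false-positive variant) by maximum
    likelihood with logit-linear covariates, performs two-step model selection
    under overdispersion-adjusted QAICc with parametric-bootstrap
    goodness-of-fit, and produces model-averaged occupancy surfaces for a
    whole district. Includes a synthetic-data generator that emulates the
    survey design for testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
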