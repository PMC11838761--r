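Package: afrimob
Title: Seasonal Relative Mobility Modelling over Administrative Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for estimating seasonal changes in human mobility from
    aggregated, differentially private origin-destination flow tables over a
    region/country/province administrative hierarchy. Builds the
    January-baseline relative mobility response, prepares zonal covariates,
    selects fixed-effect terms by a three-stage stepwise procedure, and fits
    spatiotemporal hierarchical Gaussian models (BYM2 spatial, AR1 temporal,
    space-time interaction random effects) with an exact sparse-precision
    empirical-Bayes engine, including prediction of relative mobility for
    units with missing data and residual-based calibration metrics. Ships a
    seeded synthetic-data generator emulating the privacy mechanism
    (Laplace noise plus count suppression) and country-block missingness so
    the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
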