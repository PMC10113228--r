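Package: batgapm
Title: Generalized Additive Poisson Models for Spring Emergence of Hibernating Bats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spring emergence of bats from subterranean
    hibernacula. Raw light-barrier entry/exit event streams and hourly weather
    series are aggregated into an hourly model frame; species-specific activity
    is modelled with a generalized additive Poisson model (GAPM) combining
    linear weather effects, a site factor and cyclic cubic regression spline
    smooths of sun time and day of year, fitted by penalized iteratively
    reweighted least squares with GCV smoothing selection. Downstream analyses
    extract the weather-independent ("residual") activity curve per species,
    classify species into functional groups, and compute activity-weighted
    emergence timing and synchronization metrics. A seeded synthetic-data
    module generates weather, solar events and event streams from the same
    generative model so that every stage of the pipeline can be tested against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
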