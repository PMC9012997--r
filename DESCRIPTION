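Package: otevents
Title: Detection, Regionalization, Downscaling and Projection of Compound
    Ozone-Temperature Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical framework for health-relevant compound ozone and
    temperature (o-t-) events at European monitoring stations: derivation of
    the daily maximum 8-hour running mean ozone metric (MDA8O3) from hourly
    data, pairing of ozone and temperature stations, percentile-based event
    detection, Ward hierarchical regionalization into o-t-regions,
    self-organizing-map weather typing of sea-level pressure fields,
    SMOTE-balanced logistic downscaling models with Wald backward elimination
    and cross-validated threshold calibration, monthly linear-scaling bias
    correction of Earth System Model output, and 20-year time-slice
    projections of event-frequency changes under climate scenarios. Includes
    a synthetic-data generator with known ground truth so that every stage of
    the pipeline can be validated without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
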