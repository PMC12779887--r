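Package: goosesim
Title: Multi-Species Individual-Based Model of Foraging Goose Flocks on Managed Grassland
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit individual-based simulation of wintering goose
    flocks (barnacle, greylag, pink-footed and greater white-fronted geese)
    foraging on a managed grassland landscape divided into scaring,
    accommodation and nature areas. Flocks move by a composite
    Brownian/truncated-Levy random walk, remember profitable patches, join
    conspecifics, respond to scaring, and carry an hourly energy budget that
    couples intake on growing swards to body-mass dynamics and mortality.
    The package also provides the data-to-parameter calibration procedures
    (roost detection from GPS fixes, flight segmentation, flight-time and
    step-length fitting, flock-size quantiles), synthetic-data generators for
    landscapes, weather, weight calendars and GPS tracks, damage-cost
    accounting (yield loss, scaring and appraisal costs), and factorial
    population sweeps with a normalized-coefficient importance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
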