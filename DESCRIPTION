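Package: metesar
Title: Downscaling Species-Area Relationships with the Maximum Entropy
    Theory of Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the four variants of the Maximum Entropy Theory of
    Ecology (METE) species-area relationship (SAR) downscaling: recursive or
    non-recursive occupancy downscaling crossed with a theoretical (truncated
    log-series) or observed species-abundance distribution. Provides
    numerically exact constructors for the MaxEnt spatial occupancy
    distribution and the truncated log-series abundance distribution,
    fully nested (Type IIA) quadrat SARs from spatially explicit stem maps,
    a synthetic community generator spanning complete spatial randomness,
    HEAP bisection aggregation and Thomas cluster processes, and an
    evaluation pipeline scoring each variant with the coefficient of
    determination about the one-to-one line on log richness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
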