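Package: vectornav
Title: Vector-Navigation Route Simulation and Orientation-Cage Circular Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates long-distance migratory routes under four compass
    mechanisms (geographic loxodrome, magnetic loxodrome, time-compensated
    sun compass, and the magnetoclinic apparent-inclination compass) on a
    spherical Earth, using a vendored geomagnetic reference-field model and
    a built-in solar ephemeris. Also provides the circular-statistics
    toolbox used for Emlen-funnel orientation-cage data (mean vector,
    Rayleigh test, mean-direction confidence intervals, two-sample Watson
    U2, Mardia one-way classification and concentration-homogeneity tests),
    an analysis pipeline for cage records, and a seeded synthetic
    cage-record generator for testing the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
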