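Package: allofeas
Title: Allometric Scaling and the Feasibility of Competitive Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how body-size (allometric) scaling of
    demographic rates shapes the coexistence of competing populations under
    generalized Lotka-Volterra dynamics.  Provides quarter-power scaling laws
    for metabolic, demographic and interaction parameters; generators for
    body-size-structured competition communities; feasibility-domain geometry
    (equilibrium solve, feasibility test, centroid, angular distance); a
    Lotka-Volterra integrator for dynamical spot-checks; and Monte-Carlo
    ensemble experiments that locate the carrying-capacity scaling exponent
    whose direction lies closest, on average, to the centroid of the
    feasibility domain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
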