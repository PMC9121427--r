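Package: slipgait
Title: Gait Structure and Transitions of a Bipedal SLIP Model with
    Passive Swing Legs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of a bipedal spring-loaded inverted
    pendulum (SLIP) template model extended with passive torsional-spring
    swing legs, a model family used to study gait transitions in small
    bipedal hoppers such as jerboas. Provides event-driven hybrid stride
    integration, periodic-gait search on the flight-apex Poincare section,
    pseudo-arclength branch continuation with Floquet-multiplier
    bifurcation detection, gait classification (walking, hopping,
    skipping, symmetric and asymmetric running), neutral-leg-swing-angle
    parameter sweeps, and least-squares fitting of model gaits to
    kinematic stride recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
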