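Package: rbcflow
Title: Particle Simulation of Red Blood Cell Aggregation Under Sinusoidal Pulsatile Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A two-dimensional particle model of red blood cell (RBC)
    aggregation in a rigid micro-tube under sinusoidal pulsatile flow.
    Particles obey Newton's second law with three forces: Hertzian elastic
    contact, a depletion-type aggregation force derived from a Morse
    potential, and pseudosteady Stokes drag toward an analytic pulsatile
    Poiseuille velocity field. Includes the quantification machinery for
    rouleaux formation: axial/radial shear-rate decomposition of the flow
    field, equal-area shear-decile regions of interest, normalized
    aggregated-RBC counts, mean aggregation size, center-band shear-rate
    ratios, and cycle-averaged hysteresis curves, plus a command-line
    interface for single runs and amplitude sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
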