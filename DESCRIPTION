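Package: sban
Title: Structural Bifurcation Analysis of Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts equilibrium bifurcation behavior of chemical reaction
    networks from topology alone. Builds the augmented structural matrix from
    stoichiometry, reaction loops, and conserved moieties; decomposes it into
    its finest block-triangular form to find determinant structures, buffering
    structures, and the influence graph among subnetworks; classifies which
    block determinants can change sign, which parameters can induce a
    bifurcation, and which chemicals can exhibit it. A numeric layer
    instantiates kinetic rate laws, verifies the determinant identity linking
    the structural matrix to the reduced Jacobian on the stoichiometric
    subspace, applies the associated instability criterion, and sweeps
    bifurcation diagrams over reaction parameters or conserved-quantity
    values. Ships the worked example networks, including a macrophage M1/M2
    polarization model, plus a random-network generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
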