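Package: tissuesim
Title: Agent-Based Simulation of Viscosity and Free Area in Non-Confluent Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a two-dimensional non-confluent tissue as
    polydisperse soft deformable disks with Hertzian repulsion and active
    noise in a periodic box, and analyses its glassy dynamics: pair
    correlation function, self-intermediate scattering function and
    alpha-relaxation times, cell-cell overlap statistics, Green-Kubo
    effective shear viscosity with spline plus stretched-exponential
    splicing of the stress autocorrelation, periodic Voronoi free-area
    analysis, and Vogel-Fulcher-Tammann, stretched-exponential and
    Gaussian master-curve fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
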