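Package: fclsim
Title: Particle-Based Simulation of Flat Clathrin Lattice Assembly on a
    Membrane Patch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rigid-body Brownian dynamics with stochastic binding and
    unbinding events for clathrin triskelia and membrane-resident AP-2
    adaptors in a reflecting cubic domain. Clathrin self-assembly into flat
    membrane lattices is simulated with a calibrated Doi-style association
    acceptance, Stokes-Einstein diffusion coefficients composed per cluster,
    excluded-volume move resampling, and piecewise-constant parameter
    schedules emulating growth-factor stimulation. Includes cluster dynamics
    statistics (membrane recruitment time t_c, cluster-number pattern
    frequencies, mean cluster area, dwelling times), label-mask metrics for
    electron-microscopy-derived lattice masks, a synthetic mask generator,
    and reproducible trajectory input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    tiff,
    jsonlite,
    optparse
Config/testthat/edition: 3
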