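Package: trfkin
Title: Transient Time-Resolved FRET Analysis of Nucleic-Acid Annealing Kinetics
Version: 0.1.0
Authors@R:
    person("trfkin", "maintainers", email = "trfkin@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transient time-resolved FRET measurements of
    protein-promoted nucleic-acid annealing. Provides analytic Gaussian-IRF
    reconvolution fitting of multiexponential fluorescence decays, stitching of
    multi-window streak-camera acquisitions, global three-species decomposition
    of mixture decays into stem-loop, intermediate-complex and extended-duplex
    fractions with a shared intermediate lifetime, mass-action kinetic modelling
    (two-step and three-step annealing schemes) fitted globally to
    species-concentration trajectories or stopped-flow intensity traces, and a
    synthetic-data generator emulating the droplet-microfluidic instrument
    (windowed acquisition, window-scaled IRF width, Poisson photon noise).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    numDeriv
Config/testthat/edition: 3
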