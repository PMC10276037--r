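Package: porediff
Title: Diffusion in Porous Media with Lattice Boltzmann Labels and
    Convolutional Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Procedural generation of two-dimensional porous geometries
    (random overlapping-grain packings and extracellular-space-like Voronoi
    channel networks), steady-state diffusion solved with a two-relaxation-time
    lattice Boltzmann scheme, effective-diffusion and tortuosity analysis with
    Archie-law fits, and convolutional neural-network surrogates -- including a
    self-normalization output module and Monte Carlo dropout uncertainty --
    that predict porosity and effective diffusion or reconstruct steady
    concentration fields from binary geometry images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
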