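Package: fiberCPM
Title: Hybrid Cellular Potts and Bead-Spring Fiber Network Model of Cell-Matrix
    Mechanical Reciprocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single contractile cell, described by a cellular Potts
    model, coupled through dynamic mechanosensitive focal adhesions to a
    cross-linked bead-spring fiber network representing the extracellular
    matrix. Focal adhesions are clusters of catch-slip integrin bonds whose
    size follows an ordinary differential equation driven by mechanical
    tension; the fiber network relaxes by overdamped Langevin dynamics; the
    three sub-models are advanced by operator splitting. Includes generators
    for regular, isotropic and anisotropic (von Mises oriented) networks,
    percolation tests, and the shape and alignment statistics used to analyse
    such simulations: nematic order parameter, cell eccentricity, focal
    adhesion angle distributions, binned occupancy/order time series with
    sigmoid onset fits, annulus alignment and bead displacement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
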