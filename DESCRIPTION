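Package: mapcrystal
Title: Coupled Swift-Hohenberg Dynamics and Pinwheel Statistics for
    Visual Cortical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coordinated optimization of visual cortical maps
    as coupled Swift-Hohenberg gradient-flow dynamics of a complex
    orientation-preference field and one or more real columnar fields
    (e.g. ocular dominance) on a periodic domain, with a family of
    symmetry-classified inter-map coupling energies.  Time integration is
    fully implicit (Crank-Nicolson with matrix-free Newton-Krylov solves,
    Fourier-space preconditioning, backtracking line search and
    step-doubling adaptive step control).  Includes generators for
    band-pass filtered Gaussian white noise, stripe and hexagonal initial
    conditions, subcell pinwheel detection from zero-contour crossings with
    half-integer topological charges, frame-to-frame pinwheel tracking, and
    the full crystallization-kinetics statistics toolkit (pinwheel
    densities, nearest-neighbour distance distributions, density
    variability exponents, creation/annihilation rates, survival
    fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
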