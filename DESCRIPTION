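Package: spinodal
Title: Stochastic Spinodal Porous Structure Generation, Characterization and
    Biomaterial Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates stochastic spinodal porous structures by simulating
    spinodal decomposition with a semi-implicit Fourier-spectral Cahn-Hilliard
    solver on fully periodic grids, and by a learned fully convolutional
    surrogate with circular padding that substitutes the physics solver.
    Characterizes binary voxel structures (phase connectivity, artifact
    filtering, local-thickness pore size, two-point statistics), estimates
    diffusive transport by pore-network modeling cross-checked against a voxel
    finite-volume oracle, computes effective anisotropic stiffness by
    FFT-based elastic homogenization, and designs biomaterials against
    mechanical targets: high-throughput screening for a target orthotropic
    stiffness and gradient-porosity implant volume generation with shape
    masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    graphics,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
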