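Package: megfem
Title: Continuous and Discontinuous Galerkin Finite Element Solvers for the
    MEG/EEG Forward Problem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward solvers for magnetoencephalography (MEG) and
    electroencephalography (EEG) on regular hexahedral meshes. Implements the
    subtraction source model for the dipolar EEG problem with continuous
    (trilinear nodal) and symmetric interior-penalty discontinuous Galerkin
    discretizations, Biot-Savart integration of the secondary magnetic field
    with either a nodal flux or a conservative skeleton flux reconstructed in
    the lowest-order Raviart-Thomas space, MEG transfer matrices, the Sarvas
    closed-form solution for spherical conductors, voxelized multi-layer
    sphere generators (including deliberately leaky thin-skull variants), and
    a study harness computing topography (RDM%) and magnitude (MAG%) error
    statistics against the analytic solution.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
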