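Package: pdtsim
Title: Monte Carlo Simulation of Intraoperative Photodynamic Therapy in a
    Glioblastoma Resection Cavity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coupled simulator of balloon-based intraoperative photodynamic
    therapy (PDT) for a glioblastoma resection cavity. Builds a voxelized
    synthetic phantom (residual tumor rim, intralipid-filled balloon, saline
    gaps), computes per-voxel fluence rate with Monte Carlo radiative
    transport (Henyey-Greenstein scattering, track-length estimation,
    Fresnel interfaces), integrates macroscopic singlet-oxygen PDT kinetics
    with photobleaching, Krogh-derived oxygen perfusion and a cell-kill
    threshold, and evolves tissue temperature with an explicit
    finite-difference heat solver. Fractionated illumination protocols and
    parameter sweeps (photosensitizer concentration, power, time, threshold,
    oxygen depletion) are first-class objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
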