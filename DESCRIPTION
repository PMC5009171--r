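Package: tractconcord
Title: Concordance of Probabilistic Tractography with Serial-Section
    Reconstruction on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("tractconcord", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools to validate tract localization methodology end to end on
    synthetic data: generation of crossing-fiber phantoms with a curved,
    decussating tract between a dentate-like seed and a contralateral
    thalamus-like target; probabilistic streamline tractography with
    seed/target/exclusion mask semantics and normalized connectivity maps;
    simulated serial sectioning, per-slice deformation, landmark-based
    affine registration to block-face references and iterative multivariate
    nonlinear slice-to-volume reconstruction; and voxel-wise concordance
    analysis (ROC, Dice similarity, false-negative dilation profiles) per
    region of interest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
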