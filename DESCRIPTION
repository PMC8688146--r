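Package: fdgkin
Title: Voxel-Wise Two-Tissue-Compartment FDG-PET Kinetics with
    Image-Derived Input Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamic [18F]FDG PET kinetic analysis for small-animal
    cross-over studies: a synthetic phantom generator with known regional
    rate constants, image-derived input functions corrected for partial
    volume with a fixed blood volume fraction, voxel-by-voxel weighted
    nonlinear least-squares estimation of the two-tissue-compartment
    constants k1-k4 and the glucose-transport ratio Ce/Cp = k1/(k2 +
    k3/LC), paired voxel-wise t-maps with volume-of-interest follow-up
    testing and trilinear p-map resampling, fibre-photometry 465/405 nm
    dF/F processing with response AUC, and an overlap filter chain for
    differential-expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
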