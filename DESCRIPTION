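Package: snsvta
Title: Volume-Conductor and Axon Modelling of Sacral Nerve Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the electric field and neural activation produced by
    implanted sacral nerve stimulation (SNS) leads. Builds labelled voxel
    tissue volumes (a parametric synthetic pelvis or a homogeneous block),
    implants quadripolar lead and pulse-generator geometry, solves the
    quasi-static potential on the voxel grid with a finite-volume
    conjugate-gradient scheme, drives double-cable myelinated axon models
    with the sampled extracellular potential, and summarises activation as
    the percentage of fibres firing 1:1 with the pulse train and as
    volume-of-tissue-activated rasters viewed down the lead axis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    png,
    pracma,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
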