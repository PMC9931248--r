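Package: mdtnet
Title: Automated Grading of Retinal Arterio-Venous Crossing Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, validation and severity grading of retinal
    arterio-venous crossings for automated arteriolosclerosis assessment.
    Vessel and artery/vein label rasters are refined and skeletonized,
    crossing-point candidates are detected and cut into image patches, and
    a multi-diagnosis team network (MDTNet) -- an ensemble of independently
    trained cross-entropy and focal-loss convolutional sub-models fused by
    a small trained head over frozen penultimate features -- validates
    candidates and assigns a four-level severity grade. Includes a seeded
    synthetic retinal-scene generator with planted crossings and known
    z-order and grade morphology, class-imbalance tools (focal loss,
    log-ratio class weights), a twelve-operator augmentation pool,
    subject-grouped data splitting, and agreement metrics including
    Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
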