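Package: mastosym
Title: Bilateral Symmetry-Aware Deep Learning for Mastoid Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects mastoiditis on anterior-posterior mastoid radiographs by
    evaluating the bilateral symmetry of the two ears. Implements the full
    pipeline: physical-unit ear cropping and paired-input composition, a twin
    shared-weight convolutional network with squeeze-and-excitation residual
    blocks, Log-Sum-Exp pooling classifiers, a symmetry evaluation layer with
    a symmetry-augmented loss, class activation mapping, paired diagnostic
    statistics (DeLong, Clopper-Pearson, McNemar), and a synthetic bilateral
    radiograph phantom generator so every component is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
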