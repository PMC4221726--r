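Package: tsbf
Title: Transformed Sliding Band Filter for Cell Detection in Bright-Field Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and counting of cultured cells in bright-field
    micrographs, where cells appear as dark membrane rings on a mid-gray
    background. Implements the convergence-index filter family (convergence
    index, sliding band filter, and the transformed sliding band filter that
    combines absolute gradient convergence with gradient magnitude), local
    non-maximum suppression for center extraction, Laplacian-of-Gaussian and
    intensity-threshold baseline detectors, a synthetic bright-field and
    dark-field scene generator with planted ground truth, and the
    hemocytometer counting protocol (chamber density conversion, relative
    count error rates, growth curves). Includes a command-line interface for
    batch detection, scene synthesis and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
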