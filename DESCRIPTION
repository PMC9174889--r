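Package: speckleflow
Title: Temporal Laser Speckle Contrast Analysis for Targeted Photothrombotic
    Stroke Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative pipeline for through-skull photothrombotic stroke
    imaging studies: temporal laser speckle contrast (Kt) flow mapping and the
    1/Kt^2 flow index, baseline-normalized relative cerebral blood flow time
    courses in bregma-referenced regions of interest, vascular density from
    binarized vessel images, infarct volumetry from serial coronal sections,
    and transmitted beam-spot metrics (radial profile, half-intensity distance,
    power ratio).  Includes a dynamic-speckle phantom generator -- exposure-
    integrated correlated complex Gaussian fields with flow-dependent
    decorrelation time, stroke scenario time courses, synthetic section stacks
    and beam spots -- so every stage is verifiable against known ground truth
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
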