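Package: spheromet
Title: Whole-Well Imaging, Morphometry and Viability Analysis of Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis for 3D tumor-spheroid cultures imaged
    as overlapping brightfield tiles of a whole culture well. Assembles tiles
    into a calibrated mosaic, detects spheroids as circular regions of
    interest (splitting fused clusters into overlapping circles), computes
    per-spheroid perimeter, area, volume and cell-number estimates with a
    strict minimum-diameter inclusion filter, calibrates ATP-luminescence and
    crystal-violet viability readouts, and compares treatment arms with
    two-sample t statistics and fold-changes. Includes a synthetic well-image
    generator with ground-truth annotations so that every stage of the
    pipeline can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
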