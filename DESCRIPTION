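Package: psrquant
Title: Digital Quantification of Picrosirius Red-Stained Collagen in Brightfield Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for robust, organ-transposable quantification of fibrosis on
    picrosirius red (PSR) stained brightfield sections. Provides optimized
    colour-filter detection of PSR-positive collagen (red-green contrast with a
    counterstain/chromogen noise model and chromaticity completion), tissue and
    region-of-interest segmentation (liver, lung, kidney rule sets), watershed
    separation and two-class morphological typing of collagen fibers (compact
    versus scattered), regionalized collagen metrics (collagen proportionate
    area, collagen proportion, ROI CPA), and a deterministic synthetic phantom
    generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
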