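Package: woundmetry
Title: Automated Wound Detection, Segmentation Cleanup and Size Estimation
        for Splinted-Wound Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: An image-analysis pipeline for splinted excisional wound
        photographs: orientation/scale pre-processing, wound-of-interest
        detection and fixed-size cropping, per-class score-map segmentation
        with on-the-fly augmentation, connected-component mask cleanup,
        reference-ring (splint) area calibration, missing-splint imputation,
        wound-closure time series, and robustness experiments for missing
        reference objects. Includes a synthetic phantom generator with exact
        ground-truth masks so every stage is testable without study images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, grDevices, graphics, EBImage, igraph,
        jsonlite, png, ggplot2, rlang
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 'utils.R' 'AllClasses.R' 'phantom.R' 'annotations.R'
        'preprocess.R' 'detect.R' 'segment-augment.R' 'segment-net.R'
        'segment-reference.R' 'postprocess.R' 'measure.R' 'evaluate.R'
        'pipeline.R' 'woundmetry-package.R'
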