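Package: orchardseg
Title: Citrus Tree Crown Segmentation from Nadir UAV Orchard Imagery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segmentation of individual citrus tree crowns in nadir RGB images
    of orchards taken from low-altitude unmanned aerial vehicles, robust to
    scene brightness and to weed cover. Implements selective illumination
    compensation by histogram equalization of the HSI intensity restricted to
    green-hue pixels, primary region-of-interest extraction from the
    brightness-relative G-R chromatic index with Otsu thresholding and
    morphological cleanup, an under-extraction judgement rule that switches to
    a multi-scale retinex enhanced 2G-R-B re-extraction chain on weedy scenes,
    per-region color/GLCM/uniform-LBP descriptors, and a linear support vector
    machine that confirms or rejects candidate regions. Ships a deterministic
    synthetic-orchard scene generator with per-tree ground truth, pixel- and
    tree-count evaluation metrics with ROC/AUC, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'regions.R'
    'color.R'
    'features.R'
    'classifier.R'
    'threshold.R'
    'emsrcm.R'
    'ergcm.R'
    'evaluation.R'
    'illumination.R'
    'io.R'
    'methods-accessors.R'
    'pipeline.R'
    'synthetic.R'
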