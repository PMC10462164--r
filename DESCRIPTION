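Package: cellmech
Title: Quantitative Cell Mechanics, Adhesion, Migration and Vesicle
    Proteomics Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipelines for quantifying how extracellular
    vesicles modulate vascular smooth muscle cell mechanics. Implements
    micropillar traction force microscopy with a substrate-warping
    corrected pillar stiffness model, focal adhesion detection and
    edge-distance metrics for TIRF images, an overlap-based focal
    adhesion turnover index, 2D/3D cell migration track statistics
    (forward motion index, straightness, proximity exclusion),
    thresholded colocalization coefficients with automatic threshold
    selection, and threshold-based differential proteomics set
    analytics.  Every pipeline stage is paired with a seeded synthetic
    data generator carrying ground truth, so all methods are testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBiology, Proteomics, Visualization
RoxygenNote: 7.3.3
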