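Package: LayerFusion
Title: Multiview Depth-Image Layer Features for Profile-Based Action
    Recognition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Recognizes coarse whole-body postures (standing/walking,
    sitting, stooping, lying) from synchronized multiview 8-bit depth
    image streams while preserving subject privacy. The subject is
    segmented from a per-pixel background model, split into 2N+1
    equal-height horizontal layers, and summarized per view by layer
    densities, real-range (centimeter) depths obtained through a fitted
    polynomial, inverse depths revealing hidden body volume, and a
    width/height proportion value. Per-view layer features are fused
    across uncalibrated cameras by per-layer products and a maximum
    proportion rule into view-count-independent feature vectors, which
    are classified by a single-hidden-layer neural network or an RBF
    support vector machine. A synthetic multiview depth-scene generator
    with ground-truth labels makes the full pipeline testable without
    any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    nnet,
    e1071,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Classification, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LayerFusion-package.R'
    'classify.R'
    'depth-io.R'
    'fusion.R'
    'layer-features.R'
    'pipeline.R'
    'preprocess.R'
    'synthetic.R'
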