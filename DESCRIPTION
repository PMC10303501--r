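Package: PodSeedFusion
Title: Dual-Branch CNN Feature Fusion for Identifying Near-Isogenic Plant
    Lines from Pod and Seed Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete image-analysis pipeline for distinguishing highly
    similar plant lines (e.g. mutant lines derived from one cultivar) from
    flatbed-scanner images of two organs, pods and seeds. Multi-object scans
    are segmented into size-preserving 300x300 single-object images on a black
    canvas; a built-in CNN engine provides AlexNet-, GoogLeNet-, ResNet18- and
    ResNet50-style backbones plus a small test backbone for feature extraction
    at named layers; pod and seed feature vectors of the same line are
    concatenated and classified with a support vector machine. Downstream
    tools include class-balancing augmentation with stratified 8:1:1 splits,
    confusion-matrix metrics (precision/recall/F1), Grad-CAM activation maps,
    exact t-SNE embeddings, and hierarchical clustering trees over class
    centroids with Newick export. A parametric synthetic generator renders
    paired pod/seed scans with exact ground truth, sibling (near-duplicate)
    classes and organ-complementary signal, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    tiff,
    jsonlite,
    yaml,
    e1071,
    ape,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'PodSeedFusion-package.R'
    'RcppExports.R'
    'analysis.R'
    'augmentation.R'
    'backbones.R'
    'evaluation.R'
    'features.R'
    'fusion.R'
    'nn-engine.R'
    'pipeline.R'
    'segmentation.R'
    'synthetic.R'
    'utils.R'
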