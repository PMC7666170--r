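Package: phenocyte
Title: Image-Based Phenotyping of Disaggregated Single Cells from
    Multichannel Widefield Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end image-cytometry toolkit for phenotyping
    disaggregated (suspension) single cells from four-channel widefield
    microscopy: rule-based segmentation of frames into quality-filtered
    75x75x4 single-cell patches (Otsu thresholding, watershed object
    counting, viability and stain-presence tests), a convolutional
    neural network that classifies cell phenotype from those patches
    (trained with Adam, class balancing and 90-degree rotation
    augmentation), exhaustive k-fold cross-validation, macro one-vs-all
    ROC, confusion matrices with cumulative probability curves, t-SNE
    feature embedding, and transfer learning with frozen convolution
    layers.  A built-in phantom-cell generator renders synthetic scenes
    and patch datasets with known ground truth so every stage is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    pROC,
    tiff,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'network.R'
    'evaluation.R'
    'io.R'
    'phantom.R'
    'training.R'
    'segmentation.R'
    'pipeline.R'
    'transfer.R'
    'tsne.R'
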