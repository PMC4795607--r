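Package: grainwd
Title: Weibull Texture Modeling and Sparse Multikernel LS-SVM Classification
    of Grain Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation-free quality analysis of grain images (rice, corn
    and similar scenes of many overlapping homogeneous particles). Filter
    responses from a multiscale, omnidirectional steerable Gaussian-derivative
    bank are modeled with an integral-form Weibull (generalized Gaussian)
    distribution fitted by Newton-Raphson maximum likelihood; the fitted
    shape and scale parameters over directions, scales and derivative orders
    form the image feature vector. Classification uses a least-squares
    support vector machine with a combined polynomial and radial basis
    kernel, class-weighted penalties, pivoted Gram-Schmidt sparsification of
    the kernel matrix, and particle-swarm hyperparameter tuning. A dead-leaves
    scene generator provides synthetic labeled grain images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
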