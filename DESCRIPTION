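Package: dermtex
Title: Texture-Feature Pipeline for Melanoma Versus Nevus Patch
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for texture-based discrimination of
    melanoma from benign nevus in RGB skin images.  Small square patches
    ("keypoints") are sampled from each image; every patch is summarised
    by first-order intensity-histogram statistics (mean, variance,
    skewness, excess kurtosis, min, max, on grayscale and on each RGB
    channel) and by four Haralick features of the gray-level
    co-occurrence matrix (energy, entropy, correlation, contrast)
    aggregated over five offset distances and four angles.  A zoo of
    twelve standard classifiers is trained on an image-level 75/25 split
    and ranked by test-set AUC, with full confusion-matrix metrics,
    ROC curves and Mann-Whitney rank tests of class-conditional feature
    distributions.  A synthetic two-class texture generator with
    controllable moments, spatial correlation length and colour cast
    makes the whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    e1071,
    jsonlite,
    kernlab,
    png,
    randomForest,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
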