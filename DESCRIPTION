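Package: spheropol
Title: Semi-Automated Polarity Classification of Epithelial Cell Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies the apicobasal polarity of monolayered epithelial cell
    spheroids (cysts) imaged as four-channel fluorescence z-stacks into regular,
    inverse, and aggregate/multilumen phenotypes. Implements an engineered
    feature pipeline (equatorial-plane projection, polar transformation,
    cumulative radial intensity profiles, shape descriptors, a 15-feature
    vector), decision-tree and bagged-tree classifiers with cross validation and
    two-step reclassification, a small transfer-learning style convolutional
    branch on 8-bit RGB projections, interrater-agreement statistics (percent
    agreement, Cohen's kappa with standard error and confidence interval,
    recall/precision), and a synthetic spheroid-image generator so the whole
    system can be exercised without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    rpart,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
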