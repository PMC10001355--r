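Package: pseudoseg
Title: Collaborative Teacher-Student Learning for Skin Lesion Segmentation and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised collaborative learning for dermoscopy image analysis.
    A teacher segmentation network generates pseudo-labels for unlabeled images; a
    binary quality-evaluation classifier, trained on Jaccard-graded pseudo-labels
    drawn from intermediate teacher checkpoints, screens the pool for reliable
    pseudo-labels; class activation maps from a mask-conditioned disease classifier
    are fused into a student segmentation network as localization priors; and the
    student's lesion masks are fed back as an extra input channel to improve
    three-class disease classification (melanoma, nevus, seborrheic keratosis).
    Includes a seeded synthetic dermoscopy-image generator, segmentation and
    classification metrics (Jaccard, Dice, pixel-wise rates, one-vs-rest AUC),
    desk-scale trainable convolutional networks, and a resumable pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
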