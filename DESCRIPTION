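Package: catdrift
Title: Concept-Drift-Adaptive Individual Cat Identification from Body Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual animal re-identification under concept
    drift, built around a litter-box cat monitoring scenario. Provides a
    trainable convolutional embedding network with a staged triplet-mining
    curriculum (semi-hard, hard, hardest) and global orthogonal
    regularization; a memory-bounded per-identity embedding store with
    mean-vector prioritized selection, registration and deregistration; a
    bank of classical embedding classifiers (k-nearest neighbours, random
    forest, support vector machines); one-vs-rest ROC/PR evaluation with
    confusion matrices; and a synthetic multi-cat world simulator with
    color-temperature diversification, gradual appearance drift and
    population churn for end-to-end experiments without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    png,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
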