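Package: fuzzyscreen
Title: Fuzzy-Forest Variable Screening for Correlated Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage variable screening for high-dimensional, correlated
    survey data. Stage one builds an unsupervised weighted correlation
    network (soft-thresholded Pearson adjacency, topological overlap,
    average-linkage clustering) and partitions features into approximately
    independent modules summarised by eigenfactors. Stage two screens each
    module with recursive feature elimination driven by out-of-bag random
    forest permutation importance, then selects a final feature set from the
    pooled survivors. Includes survey-weighted logistic regression with
    sandwich variances for confirmatory modelling, Mann-Whitney AUC and
    accuracy validation on a held-out wave, descriptive recodes for
    CHIS-style health surveys, and a synthetic survey generator with planted
    module structure, outcome signal, an interview-language factor with a
    rare level, and survey weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
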