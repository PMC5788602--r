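Package: spymir
Title: Two-Layer miRNA-Disease Association Prediction with Spy and
    Super-Cluster Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a binary
    association matrix, MeSH-style disease term hierarchies and a miRNA
    functional similarity matrix. Disease similarity combines two DAG-based
    semantic models with a Gaussian interaction profile kernel; miRNA
    similarity combines functional and kernel similarity. Scores come from a
    closed-form regularized least-squares classifier, refined by a spy-based
    positive-unlabeled step that extracts reliable negative pairs and by a
    Ward super-cluster layer that augments sparse positive labels. Includes
    global and local leave-one-out and repeated k-fold cross-validation
    harnesses with Mann-Whitney AUC, a planted-block synthetic data
    generator with ground truth, and broom-style tidiers plus ggplot2
    autoplot methods for results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
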