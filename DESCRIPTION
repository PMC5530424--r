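Package: kernboost
Title: Pathway-Based Kernel Boosting for Case-Control Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Network-based pathway kernels used as penalized base-learners
    inside a component-wise functional gradient boosting algorithm for
    case-control genetic association studies. Builds genetic similarity
    kernels from genotypes, SNP-gene annotation and signed gene-interaction
    networks, fits boosting models with subsampling-tuned early stopping and
    covariate offsets, predicts disease probabilities for new individuals,
    provides the logistic kernel machine score test as a single-pathway
    comparator, and ships a synthetic case-control genotype simulator for
    null and effect scenarios.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
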