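Package: trustomics
Title: Trusted Multi-Omics Patient Classification with Hypergraph
    Convolution and Evidential Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies patient samples from multiple omics blocks
    (e.g. mRNA expression, miRNA expression, DNA methylation) by
    representing each block as a k-nearest-neighbour cosine-similarity
    hypergraph, extracting per-block classification evidence with a
    hypergraph convolutional network, and fusing blocks at the evidence
    level: per-block evidence parameterises a Dirichlet opinion
    (class confidences plus a scalar uncertainty) and opinions are
    combined across blocks with the reduced Dempster-Shafer rule, so
    every prediction carries a per-sample uncertainty. Includes a
    class-conditional Gaussian simulator with planted informative
    features, a variance-filter/ANOVA-F/min-max preprocessing pipeline,
    stratified cross-validation, noise-robustness and ablation
    experiments, and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pROC,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
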