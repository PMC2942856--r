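Package: bmagene
Title: Bayesian Model Averaging for Multilocus Association Mapping with
    Gene-Gene Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping for dichotomous (case-control) phenotypes
    that explicitly models gene-gene interactions. Five elementary penetrance
    models on one or two SNPs are combined into multilocus models whose
    marginal likelihoods are available in closed form under conjugate
    beta priors, enabling a fast non-reversible Metropolis-Hastings search
    over model space and per-SNP Bayesian model-averaged association scores.
    Also provides classical comparator scores (marginal and pairwise
    interaction likelihood-ratio tests, pairwise interaction Bayes factors),
    a case-control simulation engine with linkage-disequilibrium-structured
    genotypes and three generative disease models, and evaluation metrics
    (area-detection ROC curves, AUC, location accuracy, win/loss tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
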