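Package: dmbn
Title: Bayesian Network Inference from Deletion-Mutant Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reverse engineers regulatory networks among genetically perturbed
    regulators from sparse signed differential-expression profiles of deletion
    mutant strains. Implements a deletion-mutant kernel with an exact low-rank
    feature map, the Kernel Generalized Variance surrogate for mutual
    information, a weighted-BIC structure score, template-constrained greedy
    TABU search with incremental acyclicity checking, Meek-rule conversion of
    the learned graph into a partially directed acyclic graph using template
    asymmetries as background knowledge, precision/recall and edge-orientation
    evaluation with exact binomial tests, hypergeometric functional enrichment,
    Jaccard-index baseline networks, and a synthetic perturbation-profile
    generator with a planted regulator DAG for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
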