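Package: fcalink
Title: Bipartite Link Prediction with FCA-Based Negative Sample Selection
Version: 0.1.0
Authors@R:
    person("fcalink", "maintainers", email = "fcalink@example.org",
           role = c("aut", "cre"))
Description: Link prediction on bipartite networks (chemical-disease,
    user-item, and similar two-mode association data) by biased stochastic
    gradient descent matrix factorization, with reliable negative training
    samples chosen by negative sample selection (NSS): maximal bi-cliques of
    the observed network are enumerated as formal concepts via a depth-first
    canonical (close-by-one) extension, node pairs lying in the structural
    holes of non-trivially overlapping bi-clique pairs are marked as unsafe
    negatives, and training negatives are drawn only from the unmarked
    unobserved pairs. Ships common unsupervised comparators (common
    neighbours, Jaccard, Adamic-Adar, preferential attachment, random walk
    with restart), threshold-sweep ROC/AUC and precision-recall/AUPR
    evaluation, a seeded planted-bi-clique synthetic network generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
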