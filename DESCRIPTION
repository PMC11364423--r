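Package: umistates
Title: Partitioning Single-Cell UMI Counts into Statistically
    Indistinguishable Expression States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups cells of a UMI-based single-cell RNA-seq experiment into
    the maximal subsets whose gene expression states cannot be distinguished
    given the multinomial sampling noise of the measurement.  The raw count
    matrix is modelled with a Dirichlet-multinomial marginal likelihood over
    partitions of the cells, which is maximized exactly (up to a data
    constant) by a Markov-chain Monte-Carlo search followed by deterministic
    refinement.  Includes hierarchical merging of the resulting expression
    states into a binary tree scored by log-likelihood ratios, per-gene
    differential-expression and marker scores for any branch, entropy-based
    homogeneity and completeness metrics, diversity summaries, a multinomial
    simulator for ground-truth validation, and readers and writers for the
    standard sparse count-matrix formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
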