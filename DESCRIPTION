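Package: rateshift
Title: Genome-Wide Substitution-Rate Dynamics on Time Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-gene nucleotide substitution rates on a fixed
    ultrametric time tree by maximum-likelihood branch lengths followed by a
    Poisson-observation log-Brownian rate MCMC, calls per-species fast-evolving
    genes by exact Wilcoxon signed-rank tests with FDR control, reconstructs
    ancestral rate trends, discriminates adaptive (Ornstein-Uhlenbeck) from
    drift (Brownian) evolution of rates by likelihood-ratio model selection,
    tests branch-site positive selection with empirical-Bayes site posteriors
    and post-hoc spacing filters, screens alignments for substitution
    saturation with an entropy index, relates rates to mass- and
    temperature-adjusted resting metabolic rate through phylogenetic
    generalized least squares and a bivariate Brownian correlation model, and
    tests gene-set over-representation against the single-copy-ortholog
    background. Ships a seeded synthetic-data generator with planted, labelled
    effects so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
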