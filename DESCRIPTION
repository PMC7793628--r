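Package: dynhom
Title: Bayesian Dynamic Homology Inference for Morphological Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian inference of primary homology statements and
    time-calibrated phylogeny from discrete morphological matrices. Alternative
    character codings ("homology alignments") are indexed by an integer
    homology state sampled by MCMC alongside the tree, so that the analysis
    spends more time coded under the homology hypothesis that best fits the
    phylogeny. Includes Mk-model tree likelihoods with homoplasy-based
    partitioning (implied-weights parsimony with a seeded heuristic search), a
    sampled-ancestor fossilized birth-death tree prior with fossil-site tip-age
    priors and an uncorrelated lognormal relaxed clock, ancestral-phenotype
    sampling at a focal node, and downstream phenetics (maximum observable
    rescaled distances, principal coordinates, nearest-taxon summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    coda,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
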