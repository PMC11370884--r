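Package: orthotrace
Title: Comparative Conservation of Gene Families and Pathways Across Animal Phylogenies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative ("by descent") analysis of human gene
    families and pathways across animal phylogenies: Dollo parsimony
    reconstruction of gene-family gains and losses on a rooted species tree,
    subsampling null distributions and branch z-scores for disease versus
    non-disease family classes, a maximum-likelihood pure-loss model of
    pathway content evolution with Poisson-distributed root size (ancestral
    count posteriors, loss and contraction tallies, loss-rate trees),
    pathway gene/reaction conservation summaries with a binomial GLM of
    invertebrate conservation, Shannon-index ranking of gene families and
    preranked ortholog-set enrichment analysis, and a synthetic-data
    generator that emulates all pipeline inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
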