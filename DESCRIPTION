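Package: burrowevol
Title: Comparative Molecular Evolution of Subterranean Rodent Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative molecular-evolution analysis of
    protein-coding transcriptomes from subterranean rodents and their relatives:
    one-to-one ortholog identification by best reciprocal hits, codon-aware
    alignment trimming and fourfold-degenerate-site supermatrices, maximum
    likelihood codon models (per-branch free-ratio dN/dS and the branch-site
    positive-selection test with Bayes empirical Bayes site posteriors),
    lineage rate comparison with saturation filtering, GO-category acceleration
    tests, marginal ancestral amino-acid reconstruction with parallel and
    convergent substitution detection, hypergeometric GO enrichment,
    tissue-specificity classification of candidate genes, and protein-protein
    interaction sub-network summaries. A synthetic-data module simulates codon
    and protein alignments on a phylogeny with a full substitution event log,
    so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
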