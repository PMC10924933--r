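Package: ervkit
Title: Quantitative Analysis of Endogenous Retrovirus Mobilization in the
    Bovine Germline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify germline mobilization of endogenous
    retroviruses (ERVs) from capture-sequencing read records: insertion-site
    calling with shearing-site deduplication, two-factor capture
    normalization and per-individual mobilization-rate estimation,
    expectation-maximization attribution of de novo insertions to
    tag-defined element haplotypes, simulation-based inference of the
    developmental timing of mobilization from recapture-frequency
    distributions, forward population simulation of competent and defective
    ERV copy-number dynamics, and sequence statistics on ERV element
    alignments (trinucleotide substitution spectra, four-gamete and linkage
    disequilibrium tests, divergence dating, Monte-Carlo enrichment and
    coincidence tests).  A synthetic-data module generates every input with
    recorded ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
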