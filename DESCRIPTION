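Package: dupaccel
Title: Branch-Class Codon Models for Post-Duplication Acceleration of Protein Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how long protein evolution stays accelerated after a
    gene duplication. Implements a reversible Goldman-Yang codon substitution
    model with branch-class-specific dN/dS, Felsenstein pruning likelihoods,
    and maximum-likelihood fitting of a five-class branch model on sextuplet
    gene sets (two paralogs in each of two sister species plus two outgroup
    orthologs). Provides the delta statistics contrasting pre- and
    post-duplication rates, NG86 counting estimates, duplication dating by
    synonymous divergence, gene-conversion diagnostics, synteny-based
    original/novel copy classification, family decomposition and divergence
    filters, and a codon-sequence simulator that generates fully labelled
    synthetic cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
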