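Package: synthassoc
Title: Simulation Framework for Signatures of Synthetic and Natural GWAS Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Case-control association simulations contrasting "synthetic
    associations" (significant common array markers driven by rare causal
    variants in partial linkage disequilibrium) with "natural associations"
    (common causal variants). Provides a sequentially Markov coalescent
    simulator with constant-size and bottleneck-plus-growth demographies, a
    Li-Stephens mosaic haplotype resampler, array-marker ascertainment, a
    genotypic-relative-risk disease model with case-control sampling, a
    region-wide logistic association scan with Bonferroni significance,
    genetic-map interpolation, r2/D' linkage disequilibrium statistics with
    Gabriel-style block estimation, and pooled signature statistics
    (association distance, capture curves, block capture, minor-allele
    frequency summaries, and an age-of-mutation partition).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
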