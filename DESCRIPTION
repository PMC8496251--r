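Package: epikin
Title: Kinship Corrections and Inflation of Genetic Interaction Statistics
    in Mouse Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the effect of kinship and population
    structure on genome-scan test statistics in experimental mouse crosses.
    Implements realized-genotype kinship matrices with leave-one- and
    leave-two-chromosomes-out variants, EMMA-style linear mixed model
    correction by spectral decomposition and one-dimensional grid search,
    single-locus and pairwise (epistasis) marker regressions with pooled
    permutation nulls, reparametrization of pairwise coefficients into
    directed influence coefficients across two traits with second-order
    error propagation, genomic inflation factors (lambda) with Monte-Carlo
    cross-validation, population-structure diagnostics (kinship-network
    community detection, FST, trait correlation with the leading kinship
    principal component, within-chromosome linkage disequilibrium), and a
    breeding-scheme simulator (F2, backcross, recombinant inbred lines with
    and without genomic replicates, advanced intercross, 8-founder outbred)
    so that every stage can be exercised on synthetic populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
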