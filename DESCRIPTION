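Package: silktree
Title: Parsimony Phylogenetics of Spider Silk Protein Terminal Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-family phylogenetics of spidroin (spider silk
    protein) N- and C-terminal domains: sequence-feature characterization
    (structural-motif grammar scanning, Kyte-Doolittle hydropathy profiles,
    identity and conservation statistics, pairing of N and C termini by
    their repeat flanks), Fitch parsimony tree search with bootstrap and
    Bremer decay support, partitioned and hidden branch support with the
    partition-homogeneity (ILD) permutation test, weighted duplication-loss
    reconciliation of gene trees against a species tree with exhaustive
    root selection, parsimony reconstruction of structural-motif gains and
    losses, and a synthetic-data generator that emits matched inputs with
    full ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
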