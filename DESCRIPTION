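Package: CoSAG
Title: Strain-Resolved Co-Assembly and Viability Profiling of
    Single-Amplified Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for viability-resolved single-cell microbial genomics:
    quality control of single-amplified genomes (SAGs) by single-copy
    marker completeness and contamination, pairwise genome similarity
    (fragment-based average nucleotide identity, tetranucleotide frequency
    correlation, single-copy marker homology), three-criteria strain
    grouping, iterative cross-reference chimera read cleaning, De Bruijn
    co-assembly of same-strain SAGs into composite genomes (CoSAGs) with
    assembly statistics, and capsule-level viability and composition
    profiling. Includes a synthetic-community generator emulating
    photoreactive dye (PMA) suppression of dead-cell amplification,
    Poisson droplet loading and multiple-displacement-amplification
    coverage bias and read chimerism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
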