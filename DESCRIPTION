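Package: anchorscan
Title: Anchored Gene-Neighbourhood and Provenance Analysis of Type IV
    Secretion Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises type IV secretion system (T4SS) loci
    in draft bacterial genomes. Implements profile-HMM hit filtering on
    per-domain independent E-value and profile coverage, resolution of hits
    into T4SS component categories, anchored gene-neighbourhood analysis
    around virB4 (positional abundance, component association, contig-end
    truncation, genomic-context family tables), patristic-distance
    provenance classification on a midpoint-rooted VirB4 gene tree,
    detection of tandem VirB2 pilin arrays with pairwise-identity
    statistics, greedy sequence clustering, a genome quality gate, and a
    synthetic-data generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
    phytools,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
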