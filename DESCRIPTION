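Package: ncnet
Title: Multi-Kingdom Co-Occurrence Networks and Hub Taxa from Amplicon Feature Tables
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curation, diversity analysis and compositionality-corrected
    co-occurrence network inference for paired bacterial (16S) and eukaryotic
    (18S) amplicon feature tables. Implements the N-dimensional checkerboard
    score (NC-score) on equal-frequency binned relative abundances, a
    permutation-renormalization plus bootstrap ("ReBoot") significance test,
    significance-cutoff network sweeps at several taxonomic levels,
    centrality-based hub-taxon detection with a two-tier consensus rule, and
    edge-class (inter- versus intra-kingdom) summaries. Includes alpha and beta
    diversity (Chao1, Shannon, Simpson evenness, Bray-Curtis, weighted
    UniFrac), principal coordinates, single-factor PERMANOVA with permutation
    p-values, two-group differential abundance with Benjamini-Hochberg
    correction, and a synthetic two-kingdom community generator with planted
    dependencies and hub taxa for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    ape,
    vegan,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phyloseq
Config/testthat/edition: 3
RoxygenNote: 7.3.3
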