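Package: circSponge
Title: Back-Splice Junction Discovery, circRNA Cataloguing and miRNA
    Sponge Network Inference for Sperm RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects circular RNA back-splice junctions from RNA-seq reads
    by terminal-anchor splitting against an exact k-mer genome index, applies
    stringent support/quality filters and a multi-sample presence rule, and
    assembles the surviving junctions into a quantified (BSJ reads per million
    raw reads) and classified (CDS/UTR/intronic/intergenic) circRNA catalogue.
    Infers circRNA-miRNA sponge relationships by intersecting
    partial-correlation (PCIT) negative co-abundance edges with seed-anchored
    complementarity target sites, and screens circRNA abundance against
    fixed-effect-corrected sperm motility traits. Ships a fully specified
    synthetic-data generator (toy genome, planted circles, reads, miRNA
    profiles, phenotypes) with known ground truth so every stage is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    igraph,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
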