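Package: capmapr
Title: CpG Island Mapping and Differential Methylation from CAP-seq and
    MAP-seq Enrichment Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for CpG-island (CGI) biology from affinity
    purification sequencing tracks. CAP-seq (CXXC affinity purification)
    enriches DNA fragments carrying clusters of unmethylated CpGs and
    MAP-seq (methyl-CpG binding domain affinity purification) enriches
    methylated fragments; together they delineate the unmethylated and
    methylated CGI complements of a genome. The package normalizes
    read-depth tracks to a common total, calls enrichment peaks with a
    height/length/gap rule, builds a unified CGI set across tissues,
    computes CpG composition statistics (observed/expected ratio, CpGs
    per 100 bp, sliding-window profiles, density bins), classifies CGIs
    against gene models (promoter, intragenic, intergenic), calls
    tissue- and tumour-specific differential methylation with a
    sliding-window log-ratio rule against a hypomethylated germline
    reference, and summarizes chromatin and transcription feature
    associations. A synthetic-data generator produces genomes, gene
    models, ground-truth CGI states and CAP/MAP/ChIP-like depth tracks
    with the statistical structure the analysis assumes, so the whole
    pipeline is verifiable at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
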