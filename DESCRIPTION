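Package: captor
Title: Targeted Sequence Capture Screening of CRISPR-Cas9 Off-Target Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery and validation of CRISPR-Cas9 off-target
    activity. Scans a genome for protospacer matches with mismatches adjacent
    to a PAM, analyses dCas9 ChIP-seq peak sets (guide-independent subtraction,
    replicate intersection, feature overlap, NGG PAM density with statistical
    groupings), designs tiled hybridization capture baits over 200-bp candidate
    regions, and quantifies indels from captured paired-end reads via clonal
    deduplication, pair merging, anchor-based read classification and one-sided
    Fisher's exact enrichment tests against untreated controls. Ships a
    synthetic-data generator (genome, planted off-target sites, peak sets,
    capture reads with known indel truth) so the whole screen runs end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    rlang,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
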