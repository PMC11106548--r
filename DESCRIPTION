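Package: touchcre
Title: Cis-Regulatory Element Discovery and Peak Annotation for
    Touch-Responsive Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cis-regulatory analysis of transcriptomic time
    courses in plants: strand-aware promoter extraction from genome
    sequence and annotation, scanning of degenerate (IUPAC) consensus
    motifs, exact hypergeometric and Fisher enrichment statistics with
    Benjamini-Hochberg control, de novo discovery of enriched k-mers by
    exhaustive 6-mer seeding with greedy single-base growth, comparison
    of discovered k-mers against known-motif libraries with an empirical
    shuffle null, and annotation of binding peaks by genomic feature
    category, nearest gene and TSS distance, cross-tabulated against
    differential-expression direction. A seeded synthetic-data generator
    produces toy genomes, promoters with planted motifs, expression
    tables and peak sets with known ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    rtracklayer,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomeInfoDb,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
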