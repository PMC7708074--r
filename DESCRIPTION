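Package: cracbind
Title: Downstream Analysis of CRAC RNA-Protein Crosslinking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of UV crosslinking and analysis of cDNA
    (CRAC) experiments for RNA-binding-protein target mapping. Partitions
    uniquely mapped reads into RNA classes, counts reads per transcript and
    per mRNA region (5'UTR, CDS, 3'UTR) with RPM normalization, builds
    120-bin per-transcript-normalized metagene binding profiles, computes
    replicate correlations and sample-level PCA, and calls high-confidence
    targets by RPM, enrichment over RNA-seq, and a replicate-based
    enrichment test. Includes a seeded synthetic-data generator with ground
    truth for recovery testing, and a small protein-domain toolkit
    (consensus-motif scanning, pairwise identity/similarity, greedy
    redundancy reduction) for conservation analysis of R3H-SUZ proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
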