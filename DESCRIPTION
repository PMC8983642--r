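Package: tfscope
Title: Multi-Omics Classification of Direct Transcription-Factor Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq peaks, ATAC-seq
    accessibility regions and differential RNA-seq tables to classify
    direct "active" targets of a ligand-activated transcription factor,
    and to quantify the co-occurrence and spacing of two motif families
    (e.g. Ahr and Tead) inside the same open chromatin region. Provides
    genomic interval algebra and consensus-peak construction, HOMER-style
    midpoint peak annotation, JASPAR PWM log-odds scanning with
    whole-motif containment, gene-set overlap statistics with a
    permutation null, a footprint-table top-quantile selection rule, and
    a seeded synthetic-data generator that plants motifs, targets and
    differential calls with exact ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
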