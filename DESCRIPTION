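Package: txpause
Title: Initiation Versus Elongation Control from Integrated RNA-seq and
    Pol II ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to distinguish selective control of transcriptional
    elongation from broad control of transcriptional initiation by
    integrating RNA-seq transcript abundances with RNA polymerase II
    ChIP-seq occupancy. Implements TPM normalization, gene-body occupancy
    counting with a promoter-proximal region split, metagene profiles,
    volcano classification with empirical control:control fold-change
    thresholds, dual-assay integration into net-transcriptional-regulation
    calls, AU-rich element scanning with exact enrichment tests, small
    open reading frame detection in long non-coding RNAs, and a Shannon
    information-content calculus for regulatory selectivity. Includes a
    seeded synthetic-data generator with ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
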