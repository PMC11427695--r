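Package: mgidemux
Title: Demultiplexing Toolkit for MGI DNBSEQ FASTQ Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Streams MGI-format FASTQ runs and assigns reads to samples via a
    mismatch-tolerant index lookup table built by Hamming-ball expansion of
    the sample-sheet indices. Auto-detects the barcode template (order,
    lengths and orientations of i7/i5/UMI in the read-barcode tail), rewrites
    reads with Illumina- or MGI-dialect headers and file names including
    UMI-aware headers, writes mergeable per-lane demultiplexing and quality
    reports, and ships a seeded simulator generating ground-truthed synthetic
    runs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    Biostrings,
    ShortRead,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
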