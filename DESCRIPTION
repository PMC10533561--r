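Package: hybseq
Title: Hybridoma Antibody Variable-Domain Amplicon Sequencing Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end processing of barcoded paired-end amplicon sequencing
    of hybridoma immunoglobulin transcripts: inline-barcode demultiplexing,
    chain assignment, quality trimming and paired-read merging; abundance-based
    denoising into amplicon sequence variants; removal of the aberrant Sp2/0
    myeloma kappa transcript; IMGT numbering and framework/CDR segmentation of
    translated variable domains with validity filtering; replicate-consistency
    star scoring of curated V_L/V_H sequences and cohort summaries; and
    deterministic design of Gibson-Assembly-ready gene fragments for
    recombinant-mAb and scFv expression constructs. A synthetic plate
    simulator with known ground truth makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
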