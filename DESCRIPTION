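Package: longtrx
Title: Full-Length Transcriptome Analysis of Long-Read Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of full-length transcript
    models obtained from long-read (single-molecule) cDNA sequencing of
    cancer and normal cell lines, with short-read support data. Implements
    transcript novelty classification against a reference annotation,
    validation of transcription start sites against CAGE and histone-mark
    peak sets, consensus long non-coding RNA filtering with cancer-specific
    lincRNA set logic and co-expression target prediction, local alternative
    splicing event enumeration with a Jaccard-based isoform-usage divergence
    score, and multi-criteria fusion-transcript detection with short-read
    junction support filtering. A synthetic-data module generates every
    input class with planted ground truth so the whole pipeline can be
    exercised and validated without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
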