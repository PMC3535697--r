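Package: altevents
Title: De Novo Cassette Exon Event Annotation from Transcript Isoform Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives de novo alternative-splicing event annotations (cassette
    exons) from transcript isoform models reconstructed from RNA-seq, such as
    Cufflinks GTF or Scripture BED12 output. Gene exon unions are partitioned
    into minimum non-overlapping exon units, isoforms are projected onto the
    units to form per-unit inclusion count strings, and cassette exons are
    detected from consecutive-exon chain evidence (an inclusion chain
    flank-cassette-flank against a skipping chain joining the flanks
    directly). Events are serialized as a MISO-consumable GFF3 dialect.
    Includes the matching evaluation protocol (exact-trio matching, rate of
    known events, recall, read-support filtering), a ground-truthed synthetic
    annotation generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    IRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
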