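Package: fqdedup
Title: Memory-Bounded De Novo Removal of PCR Duplicates from FASTQ and FASTA Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming identification and removal of PCR duplicates from
    single-end and paired-end sequencing reads without alignment to a
    reference genome. A sequence-based engine sorts reads by sequence with a
    memory-budgeted external merge sort and removes duplicates in a single
    pass over the sorted stream, under three duplicate definitions: exact
    full-length matches ("tight"), prefix matches in the style of FastUniq
    ("loose"), and bounded Hamming distance between adjacent sorted reads
    ("tail-hamming"). A separate in-memory "fast" mode removes exact
    duplicates using sequences packed into 64-bit words while preserving
    input order. Includes a seeded synthetic-library generator with a
    ground-truth manifest and naive reference implementations of every mode
    for verification. Reads and writes FASTQ and FASTA, plain or
    gzip-compressed; read identifiers, sequences and qualities are never
    altered.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    data.table
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
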