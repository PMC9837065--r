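Package: satscreen
Title: Screening and Quantification of Pericentromeric Satellite Transcripts
    in Barcoded Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies transcripts of pericentromeric satellite
    repeat families (human HS2/HS3, built on ATTCC units, and mouse major
    satellite MaSat, derived from GAAAAATGA) in barcoded droplet single-cell
    RNA-seq reads. Reads are demultiplexed into annotated cell clusters by
    their cell barcodes, clusters are verified by marker-gene content,
    individual cDNA reads are classified against repeat-family k-mer
    signatures by window coverage, and per-cluster expression is reported as
    transcripts per million (TPM) after UMI deduplication. Also implements
    k-mer-frequency design of satellite hybridization oligonucleotides, a
    fully deterministic synthetic-data generator (barcoded FASTQ with known
    cluster structure and spiked satellite fractions, plus two-channel FISH
    images with known signal geometry), and quantification of nuclear versus
    cytoplasmic FISH signal area in microscopy fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    EBImage,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
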