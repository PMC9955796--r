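Package: abcfam
Title: Characterization of ABC Transporter Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for genome-scale characterization of ATP-binding
    cassette (ABC) transporter families. Compiles and scans extended
    PROSITE-style protein motif patterns (including a hydrophobic-class
    extension), assembles Walker A / ATP-binding / Walker B triplets into
    nucleotide-binding domains and classifies them, maps conserved-domain
    arrangement strings onto structural types and transport/translation
    roles, derives consensus patterns and per-column information content
    from aligned motif blocks, censuses cis-regulatory elements in
    promoter regions against an IUPAC consensus dictionary, screens
    expression via RPKM with hierarchical clustering, computes relative
    transcription with the 2^-ddCt method over multiple reference genes,
    reports protein physical properties (molecular weight, isoelectric
    point, intron counts), and generates fully-ledgered synthetic cohorts
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    seqinr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
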