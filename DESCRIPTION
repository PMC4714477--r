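Package: rnaedit
Title: Calling A-to-I RNA Editing Sites from Paired RNA and DNA Sequencing
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for calling high-confidence RNA-DNA
    differences (RDDs) from aligned RNA-seq reads and matched whole-genome
    DNA sequencing. Candidate RNA variants are called from quality-filtered
    pileups, screened against alignment-artifact regions (homopolymers,
    repeats, multi-mappability, self-chain), subtracted against deep genomic
    coverage, strand-resolved through gene annotations, and classified into
    edit classes with canonical A-to-I selection. Downstream analyses cover
    genic context and coding consequence, sequence-context matrices,
    category enrichment over an expressed-gene universe, RPKM and splice
    junction quantification (including the ADAR p110/p150 isoform
    junctions), cross-sample sharing statistics, editing matrices with
    coverage masking, and per-site correlation of editing frequency with
    editing-enzyme expression. A deterministic synthetic-data generator
    with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
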