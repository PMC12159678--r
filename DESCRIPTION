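Package: erviso
Title: Locus-Level Quantification and Isoform Contribution Decomposition
    for an LTR-Embedded Endogenous Retrovirus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the transcripts of a repeat-embedded
    endogenous retrovirus locus without deconvolution, using unique
    quantification regions derived from overlapping transcript models;
    to score canonical 5' LTR promoter activity from splice-junction
    reads; to decompose composite gene expression into per-transcript
    contributions with a regression model and a per-sample log2
    contribution ratio; to summarize CpG methylation over the LTR
    promoter and detect consensus-divergent substitutions against
    active LTR references; and to compute single-cell expressing-cell
    fractions and compositions. A synthetic-data module generates every
    input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    Biostrings,
    Matrix,
    jsonlite,
    yaml
Suggests:
    GenomicAlignments,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
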