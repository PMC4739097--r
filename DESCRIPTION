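Package: TINseq
Title: Transcript Integrity Scoring and Degradation-Aware Correction for RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the transcript integrity number (TIN), a per-transcript
    RNA degradation score derived from the Shannon-entropy uniformity of read
    coverage sampled along each transcript, together with its companion
    procedures: the sample-level median TIN (medTIN), RNA fragment-size
    estimation from paired-end alignments with intron subtraction, loess-based
    correction of gene-level read counts against TIN, 3' tag counting, and
    gene-body coverage profiles. Includes a synthetic degraded-library
    simulator that emits BED12 gene models, spliced paired-end alignments and
    a per-transcript ground-truth table, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Sequencing, RNASeq, QualityControl, Coverage, Normalization
RoxygenNote: 7.3.3
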