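Package: anchorvar
Title: Reference-Free Detection of Sample-Dependent Transcript Sequence
    Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sample-dependent transcript sequence variation directly
    from raw RNA-seq reads, without alignment to a reference genome. Reads are
    decomposed into pairs of adjacent fixed-length k-mers: a constant "anchor"
    followed by a variable "target". Anchors whose target composition differs
    across samples are found with a train/test split, alternating maximization
    of sample and target embeddings, and a closed-form concentration bound,
    followed by Benjamini-Hochberg correction. Significant anchors are screened
    against adapter/vector sequences, placed on an optional reference genome by
    an exact spliced matcher (or imported SAM alignments), and classified into
    mechanistic categories (allelic variation, intron retention, cryptic
    splicing, differential homolog expression, unaligned targets).
    Metadata-dependent anchors are called by L1-penalized multinomial
    regression on top-target counts, with one-way ANOVA/Tukey HSD pairwise
    tests summarized as compact letter displays. Includes a synthetic read
    generator that plants ground-truth events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    glmnet,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr,
    BiocGenerics,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
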