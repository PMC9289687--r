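Package: methploid
Title: Methylome Dosage-Response Analysis for Whole-Genome Duplication Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    experiments that compare cytotypes of the same genotype (for example a
    diploid against its colchicine-induced autotetraploid). Provides
    methylcytosine calling from per-cytosine bisulfite counts with a
    binomial test against the conversion-error rate and per-context
    Benjamini-Hochberg correction, weighted methylation levels for
    arbitrary regions, metagene profiles over gene bodies with 2-kb
    flanks, sliding-window detection of differentially methylated regions
    under context-specific site-count and effect-size criteria, and
    transposable-element proximity analyses relating methylation and
    expression of protein-coding genes and long non-coding RNAs. A
    synthetic-data generator produces genomes, annotations, per-cytosine
    counts and expression tables with planted ground truth so that every
    stage can be exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
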