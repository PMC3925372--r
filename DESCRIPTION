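Package: srnapipe
Title: Small RNA-Seq Tag Profiling, Tag-Count Differential Abundance, and
    Phased siRNA Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for plant
    sRNA libraries: adapter trimming and tag collapsing, hierarchical
    annotation of tags against a genome feature set with a strict
    category-priority rule, an exact tag-count differential-abundance
    statistic with a two-tailed rule, six-rule plant miRNA target
    prediction over ungapped duplexes with G-U wobble scoring, hairpin
    screening of unannotated tags for novel miRNA candidates, 21-nt
    phase-register analysis of trans-acting siRNA (TAS) loci with
    initiator-miRNA network construction, and quantification of
    natural-antisense-transcript siRNAs over overlap and whole-gene
    regions. Includes a deterministic synthetic-data generator that
    emulates the statistical structure of plant sRNA libraries so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
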