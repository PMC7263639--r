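Package: sexdim
Title: Sex-Biased Liver Transcriptome and Histone-Mark Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sexually dimorphic gene expression and its
    chromatin correlates in mouse liver. Implements a negative-binomial exact
    test for differential expression with gene classifications (liver-expressed,
    sex-biased, stringently sex-independent, knockout-responsive), a percent
    feminization index for female-biased genes, reads-in-peaks-per-million
    (RiPPM) and static-site normalization of ChIP-seq window counts,
    multi-window-size differential histone-mark site detection with
    cross-window consolidation, GREAT-style basal-plus-extension regulatory
    domain mapping of sites to genes, eight-way histone-mark pattern
    classification, and Fisher exact enrichment scoring. A negative-binomial
    synthetic data generator produces expression matrices and window count
    tracks with known ground truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
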