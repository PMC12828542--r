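Package: methexpr
Title: Integrative Differential Methylation and Expression Analysis for
    Two-Factor Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links DNA-methylation changes to gene-expression changes in a
    2x2 metabolic-state by temperature design. Implements low-count gene
    filtering, a negative-binomial Wald engine for main-effect and
    interaction contrasts, CpG masking and beta/M-value differential
    methylation, promoter and gene-body region assignment, correlation-based
    calling of differentially methylated and expressed genes (DMEGs) with
    four-way categorisation, cross-condition overlap classification,
    regulator and cell-type cross-referencing, and PWM motif enrichment
    around methylated loci against sampled promoter backgrounds. Ships a
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
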