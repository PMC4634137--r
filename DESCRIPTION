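Package: hcmotif
Title: Cell-Type-Specific Promoter Motif Enrichment from Inner-Ear
    Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers transcription-factor regulons active in inner-ear hair
    cells from multi-cell-type expression matrices. Provides detection
    filtering, quantile normalization, two-way ANOVA differential
    expression with Benjamini-Hochberg correction, expression-pattern
    clustering, strict cell-type marker calling, strand-aware promoter
    extraction, PWM log-odds scanning, hypergeometric motif
    over-representation testing with TSS-positional analysis and window
    narrowing, simplified k-mer motif discovery, ChIP-target intersection,
    cross-species regulon conservation tests, and rank-based
    expression-shift tests. A ground-truthed synthetic-data generator
    emulates the sorted-population study design (two organs, three cell
    types, replicated) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    limma,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
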