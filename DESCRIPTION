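Package: silencescan
Title: Transcription-Factor Silencing Analysis by MA-Plot Differential
    Expression, Binding-Site Scanning and Histone Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-condition transcription-factor
    knockdown experiments read out by RNA-seq and ChIP-seq. Implements
    gene-level RPKM quantification over union-exon gene models, the
    MA-plot random-sampling (binomial) differential-expression test with
    Benjamini-Hochberg correction and a composite two-timepoint calling
    rule, association of binding-site peaks with regulated genes,
    conserved core-motif and palindrome scanning around peak summits,
    contingency-table enrichment statistics, and histone-modification
    footprint and silenced/control ratio profiling around transcription
    start sites. A fully seeded synthetic-data generator emits
    self-consistent annotation, counts, peaks, sequence, conservation and
    coverage inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
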