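Package: methconcord
Title: Strand-Concordant Differential Methylation Calling for Two-Colour
    Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential DNA-methylation analysis of two-colour,
    strand-paired methylation tiling arrays, as used to profile day-17
    bovine conceptuses produced by assisted reproduction. Provides LOESS
    intra-array and scale/quantile inter-array normalisation of M-values,
    group-means linear-model fitting with empirical-Bayes moderated
    t-statistics, a high-stringency sense/antisense probe concordance rule
    for locus-level calling, CpG island/shore/shelf/open-sea context
    classification, gene-body, CTCF-site and miRNA overlap annotation, a
    pooled two-proportion test for feature under-representation, and
    treatment/region/direction summary reporting with Venn-style overlap
    and direction-discordance accounting. A synthetic-array generator with
    planted ground truth emulates the 36-array three-treatment,
    three-region design for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    limma,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
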