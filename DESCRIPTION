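Package: iucExpr
Title: Expression Clustering and Positional Dysregulation Analysis for
    Invasive Urothelial Carcinoma
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the tumor-expression analysis of invasive urothelial
    carcinoma from gene-level RNA-seq count matrices: negative-binomial
    differential expression of tumors against normal tissue with
    median-of-ratios normalization, resampling-based consensus clustering of
    tumors into mutation-associated groups, per-sample z-score significance
    against the normal baseline with Jaccard set-coherence testing, a
    discriminating-gene classification rule contrasting the two tumor
    clusters, a sliding-window hypergeometric scan for chromosomal hotspots
    of dysregulated genes, and gene-set over-representation analysis against
    GMT collections.  A synthetic-data generator plants differential
    expression, cluster structure, and positional hotspots with ground-truth
    tables so every stage of the pipeline has a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
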