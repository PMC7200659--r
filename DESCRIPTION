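Package: memsig
Title: Signal-Detection Analysis of Heritable Methylome Repatterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heritable differential DNA methylation from bisulfite
    sequencing count data using a signal-detection approach: per-cytosine
    Hellinger divergence against a pooled reference centroid, model-based
    calling of differentially methylated positions (DMPs) with a fitted
    gamma null and a Youden-index cutoff, classifier-based validation and a
    four-method caller benchmark, count-GLM testing of differentially
    methylated genes (DMGs), transgenerational heritability set logic with
    a recurrence null simulation, transposable-element proximity
    enrichment, and downstream discrimination statistics (Ward clustering,
    PCA-LDA, methylation-expression association). Includes a synthetic
    bisulfite data generator with known ground truth so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    glmnet,
    MASS,
    fitdistrplus,
    stats,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
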