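Package: txherit
Title: Quantitative Genetic Analysis of Blood Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the heritability of gene expression in outbred
    livestock cohorts with an animal model fitted by average-information
    REML against a company-blocked VanRaden genomic relationship matrix,
    and estimates genetic correlations of expression with performance and
    disease-resilience phenotypes by bivariate REML. Includes TMM-based
    count normalization, phenotype derivation (health scores, treatment
    rates, mortality codings, residual feed intake), 0.5-Mb window
    summaries of heritability across the genome, over-representation and
    pre-ranked gene-set enrichment analysis with signed-significance
    clustering, and a synthetic-cohort simulator with known ground truth
    for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    parallel,
    Matrix,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
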