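Package: loadalign
Title: Aligning Mouse Genotype-by-Diet Transcriptomic Effects to Human
    Alzheimer's Disease Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for relating factorial mouse brain transcriptomic
    experiments to human late-onset Alzheimer's disease (LOAD) references.
    Provides housekeeping-gene geometric-mean normalization of
    NanoString-style count panels, per-gene factorial linear modelling with
    diet-by-genotype interaction terms, Pearson correlation of model
    coefficients against human co-expression module and molecular-subtype
    log2 fold-change references, extraction of directionally coherent genes,
    preranked gene-set enrichment (weighted Kolmogorov-Smirnov) with
    over-representation analysis and PCA of normalized enrichment scores,
    cerebellum-referenced standardized uptake value ratio (SUVR) analysis of
    PET/autoradiography volume-of-interest tables with PCA-based region
    selection, and the accompanying univariate study statistics (two-way
    ANOVA with Tukey HSD, repeated-measures ANOVA, half-LLOD imputation).
    A synthetic-data generator with planted effects makes every stage
    verifiable without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
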