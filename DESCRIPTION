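Package: cytonet
Title: Constrained Principal Component Analysis of Plasma Cytokine Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for group-level network analysis of multiplex cytokine
    panels. Implements the full analysis pipeline for a four-group child
    plasma study design: limit-of-detection handling (below-LOD zeroing and
    exclusion of analytes undetectable in over 10 percent of samples),
    Winsorization of extreme values at |3.29| standard deviations, rank-based
    inverse normal (Blom) transformation, per-analyte covariate-adjusted
    hierarchical regression with Holm-Bonferroni post hocs, group-mean z-score
    heatmap profiling, and constrained principal component analysis (CPCA):
    regression of the cytokine matrix on group membership followed by PCA of
    the predicted scores, Varimax rotation with Kaiser normalization,
    scree-based component retention, group-component correlations and
    activated/inhibited network assignment. A synthetic-cohort generator
    plants known group-driven cytokine networks with lognormal concentrations,
    LOD censoring and outliers, so every stage is verifiable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    MASS,
    jsonlite,
    yaml,
    pheatmap,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
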