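Package: antcaste
Title: Tracking Canalized Caste Differentiation Across Developmental
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how the gyne (reproductive) and worker
    castes of social insects diverge and canalize across ordered
    developmental stages, from per-individual transcriptomes. Implements
    backward caste prediction across stages (batch normalization, PCA
    projection, ANOVA-based axis selection and a two-class linear
    discriminant), developmental-potential scores based on Manhattan
    distances to next-stage caste centroids, gene-level canalization
    scores combining a caste t score with a trend test on its absolute
    value across stages, sample-similarity trajectory networks,
    cross-species stage alignment through one-to-one orthologues,
    body-size-adjusted differential expression, two-phase (hinge)
    body-length threshold regression, and a fully parameterized
    synthetic-data generator with recorded ground truth for validating
    every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
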