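Package: hetscore
Title: Heterogeneity-Aware Scoring of Arrayed CRISPR-Cas9 Image-Based Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores arrayed CRISPR-Cas9 image-based screens at single-cell
    resolution. Each well holds a mixed population of transfected (T(+)) and
    non-transfected (T(-)) cells; a bootstrapped, cross-validated L1-penalized
    logistic classifier is trained per well to separate the two populations,
    and the transformed misclassification error scores the perturbation.
    Individual phenotypically perturbed cells are gated by their classifier
    predicted value and profiled. Also provides in-well standardization,
    well QC, B-score plate correction, a between-well Mahalanobis baseline,
    Kolmogorov-Smirnov phenotypic scores, Tukey-fence hit calling,
    hypergeometric gene-set enrichment, CRISPR guide selection rules,
    barcode deconvolution QC, and a synthetic-screen generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    data.table,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape
Config/testthat/edition: 3
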