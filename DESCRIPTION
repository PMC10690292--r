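Package: cytoprofile
Title: Image-Based Profiling Pipelines for High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bioinformatics processing of image-based (Cell Painting style)
    morphology profiles: reading and writing profile tables and plate maps,
    merging CellProfiler-style single-cell compartment tables, aggregation of
    single cells to well-level profiles, plate-map annotation, robust
    normalization against negative controls (standardize, MAD-robustize and
    ZCA sphering for batch correction), auditable feature selection
    (near-zero-variance, missingness, correlation and blocklist filters), and
    a multi-class cell-injury classification workflow with plate, treatment
    and well holdouts, class-weighted multinomial logistic regression with
    randomized hyperparameter search, and evaluation against a
    label-permutation baseline. A synthetic-screen generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    arrow,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
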