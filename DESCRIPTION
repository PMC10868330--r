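Package: tmescope
Title: Tumor Microenvironment Annotation, Label Similarity Maps, Malignancy
    Classification and Spatial Structure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for dissecting the tumor microenvironment (TME) in
    single-cell and spatial transcriptomics data. Trains transferable
    cell-subtype classifiers from annotated references using a
    marker-weighted multinomial likelihood with core-cell selection and
    entropy-based feature selection; quantifies the correspondence between
    subtype labels defined in different studies through Jaccard similarity
    maps with hierarchical clustering and multidimensional scaling views;
    identifies malignant cells without an internal reference using a
    gradient-boosted classifier trained on the union of recurrent bulk
    tumor-versus-normal genes and high-variance single-cell genes; and
    analyzes spatial transcriptomics slides for cluster boundaries,
    ligand-receptor interactions by permutation testing, signature scoring,
    and spatial structure detection with global and local Moran's I.
    Includes seeded synthetic-data generators with planted ground truth for
    every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    xgboost,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
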