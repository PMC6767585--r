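Package: weedmapr
Title: Weed Density Mapping from Multispectral UAS Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for mapping ordinal weed
    density states (black-grass, Alopecurus myosuroides, in winter wheat)
    from multispectral unmanned-aerial-system imagery. Computes per-pixel
    vegetation indices (GNDVI, NDVI) from four-band scenes, overlays a
    20 x 20 m ground-truth plot grid, subsamples each plot into a 4 x 4
    grid of subplot tiles, curates the tiles (class balancing,
    clean/artefact partitioning, coverage bracketing), trains a compact
    convolutional neural network on GNDVI tiles, upscales subplot
    predictions to plot level by the median rule, and scores results with
    one-vs-rest multiclass ROC/AUC, Cohen's kappa, weighted kappa and
    DeLong AUC comparison. A synthetic-scene generator produces
    multispectral fields with spatially aggregated weed patches, realistic
    class imbalance and non-crop artefacts, so the whole analysis -
    including leave-one-field-out cross-validation and temporal grouping -
    runs and is tested without any external imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
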