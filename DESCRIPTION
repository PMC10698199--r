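Package: covparc
Title: Metabolic Covariance Parcellation of Brain Seed Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariance-based parcellation of a seed brain structure (the
    hippocampus) from subject-level glucose-uptake volumes, with the
    downstream analyses of a metabolic-connectivity study: bootstrap
    consensus k-means clustering with split-half adjusted-Rand stability
    selection, seed-based metabolic covariance network maps fitted by
    parcel-level linear models with false discovery rate control,
    subregional group statistics with cerebrospinal-fluid biomarker
    stratification, spatial association of network maps with reference
    maps under permutation nulls, and construction of regional gene
    expression matrices from donor microarray tables using differential
    stability probe selection and robust sigmoid normalization.  A
    synthetic-data module emulates the statistical structure of the
    study inputs so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    car,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
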