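Package: heqr
Title: Homology-Based Emphysema Quantification from Lung CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pulmonary emphysema on 2-D CT slices by combining the
    classical low-attenuation area percentage (LAA%) with topological
    descriptors: the Betti numbers of the low-attenuation lung set computed
    over a Hounsfield-unit threshold filtration, normalized by lung area.
    Includes threshold-based lung segmentation with border-component removal,
    a synthetic chest-phantom generator with ground-truth lesion topology,
    construction of per-slice feature vectors across threshold sub-ranges,
    Random-Forest prediction of ordinal visual emphysema scores under
    leave-one-patient-out cross-validation with hyperparameter grid search and
    importance-based feature selection, and the associated evaluation
    statistics (Spearman correlation, contingency tables, quadratic-weighted
    kappa, exact McNemar test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
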