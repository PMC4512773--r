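Package: metabootr
Title: Robust Non-Redundant Taxonomic Biomarker Discovery via mRMR and
    Stratified Bootstrapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers non-redundant taxonomic biomarkers from microbial
    community abundance tables. Combines minimal-redundancy
    maximal-relevance (mRMR) feature selection under the mutual
    information difference (MID) criterion with stratified bootstrap
    resampling and occurrence ranking, so that the selected taxa are
    both discriminative and stable under resampling. Ships ground-truth
    synthetic benchmark generators (normal, gamma and mixture abundance
    designs with redundant marker groups), preprocessing for abundance
    tables (relative-abundance normalization, sparsity filtering,
    three-level discretization), a Wilcoxon rank-sum comparator, an
    RBF-SVM cross-validation evaluator, and an exact permutation test
    for small sample sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
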