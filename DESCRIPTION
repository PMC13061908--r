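Package: rinsemet
Title: Mouth-Rinse Metabolomics Stress-Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discovery pipeline for salivary (mouth-rinsed water)
    metabolomic stress biomarkers: synthetic study generation with
    participant, dilution and censoring structure; feature-inclusion
    filtering on analytical QC criteria with below-LOD substitution and
    z-score standardisation; cross-sectional (Mann-Whitney U with
    Benjamini-Hochberg correction) and longitudinal (Friedman with
    Nemenyi post-hoc) screening; exhaustive single-feature and
    metabolite-ratio threshold classifiers fitted by the Youden index
    and evaluated by leave-one-out cross-validation nested in a
    participant-level bootstrap, with DeLong inference on the AUC;
    covariate-adjusted and sex-stratified robustness checks; and
    PCA/Ward-clustering overviews.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
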