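Package: fwmrs
Title: Feature-Weighted Maximum Representative Subsampling for Selection-Bias Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Debiases a non-representative tabular sample against a
    representative reference by iteratively dropping the samples a domain
    classifier most confidently flags as non-representative (maximum
    representative subsampling), with softmin-transformed feature
    importances downweighting highly biased features so that fewer samples
    must be dropped. Includes the unweighted MRS special case, kernel mean
    matching and propensity-score-adjustment baselines, a sample- and
    feature-weighted maximum mean discrepancy, the corrected repeated
    k-fold cross-validation t-test, and a synthetic-bias benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    kernlab,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
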