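Package: cpctriage
Title: Referral Triage with Clinical Prioritisation Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts the Clinical Prioritisation Criteria (CPC) condition
    and urgency category (1, 2 or 3) for free-text specialist outpatient
    referrals. CPC conditions are predicted with a weighted ensemble of
    text similarity metrics (cosine, Euclidean, Jaccard, normalised
    Levenshtein), k-nearest neighbours, supervised multiclass classifiers,
    self-training semi-supervised learning, or seeded k-means clustering;
    the urgency category is then read off the per-category CPC criteria
    text. Ships a synthetic corpus generator emulating the statistical
    structure of real referral data (label scarcity, class imbalance,
    morphological variants and typos) so the whole pipeline is testable
    without access to any clinical data, and an evaluation suite reporting
    the level of agreement with historical categorisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    ranger,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
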