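Package: specs
Title: Non-Parametric Specificity Scoring for Unbalanced Sample Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies molecular features (typically genes) that are
    specifically present or absent in one of several sample groups using
    SPECS, a rank-based AUC-type exceedance probability that uses every
    replicate and tolerates strongly unbalanced group sizes. Also provides
    five classical specificity metrics (z-score, Gini coefficient, Tau,
    TSI and the Jensen-Shannon distance score) computed on mean-collapsed
    tissue profiles, median-of-ratios count normalization, selection of a
    low-abundance stable background gene set, a spike-in benchmarking
    harness that induces artificial specificity and compares metrics by
    score ranks, and a negative-binomial count simulator for fully
    reproducible testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
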