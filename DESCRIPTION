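Package: baconet
Title: Balanced Correlation Networks for Gene Buffering Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene buffering relationships by correlating CRISPR
    knockout fitness effects (Chronos scores) with mRNA expression across
    panels of cancer cell lines, and corrects the resulting correlation
    network post hoc with a balancing transform (BaCoN) that penalizes
    gene pairs whose partners have many similarly extreme coefficients.
    Includes readers for DepMap-dialect matrices, a priori normalizations
    (ComBat batch adjustment, Cholesky/PCA/ZCA data whitening), multiple
    linear regression association scores, a six-metric evaluation stack
    with an empirical false discovery rate built from rule-labeled true
    and false positives, a high-confidence pair-set procedure, and a
    synthetic data generator with planted buffering pairs and lineage
    co-expression confounders for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    sva
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
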