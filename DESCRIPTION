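Package: pascrosstalk
Title: Crosstalk-Aware Pathway Activity Scores for Prognostic Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores pathways per tumor sample by dichotomized gene ranks
    (pathway activity scores, PAS), factors overlapping pathway pairs into
    crosstalk sub-pathways, screens features by univariate Cox survival
    association (sure independence screening plus Benjamini-Hochberg FDR),
    discovers moderate/aggressive survival subtypes by K-means clustering,
    and classifies new cohorts with a k-nearest-neighbor model. Ships a
    multi-cohort synthetic-data generator with planted prognostic subtypes
    so the whole pipeline is testable without external downloads, plus
    evaluation metrics (Harrell's C, IPCW Brier score, Kaplan-Meier and
    log-rank analysis, ROC-AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    class,
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
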