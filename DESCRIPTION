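Package: ocrnet
Title: Consensus Co-Expression Networks and Organoid Drug-Response Models
    for Chemotherapy Response Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomarker discovery from matched tumor and
    patient-derived organoid expression cohorts. Builds signed weighted
    gene co-expression networks per cohort, calibrates topological overlap
    matrices by full quantile normalization and combines them into a
    consensus network, detects modules and computes eigengenes and
    consensus module membership (kME). Modules are screened by a dual
    criterion (Cox proportional-hazards association of tissue eigengenes
    with survival, and tumor-organoid eigengene concordance), hub genes
    are extracted, and an ensemble drug-response model (random-forest
    permutation-importance gene filter followed by ridge regression) is
    trained on organoid IC50 data. Patient-level drug-resistance scores
    are dichotomized at a maximally selected rank-statistic cutpoint and
    evaluated by Kaplan-Meier curves and log-rank tests. Includes a
    seeded synthetic-cohort generator with planted module structure,
    drug effects and survival outcomes for end-to-end validation, plus
    baseline gene-selection procedures and hypergeometric
    over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    limma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
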