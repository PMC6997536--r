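Package: miragg
Title: Rank Aggregation and Benchmarking for miRNA Target Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines ranked miRNA target prediction lists from several
    sources into a single reranked, scored list using order-statistic rank
    aggregation (mean, median, min, geometric mean, Stuart, and the
    Bonferroni-corrected beta order-statistic rho score), with max-rank
    imputation for interactions missing from a source. Ships the full
    evaluation protocol used to compare prediction tools: ROC and partial
    ROC at high specificity, precision-recall and average precision,
    cumulative F-score curves, prevalence-matched replicate subsampling,
    repeated-measures ANOVA with a Monte-Carlo Dunnett post-test, and a
    synthetic multi-source prediction generator with known ground truth so
    the whole pipeline is testable without external databases. Includes
    pathway ranking by the proportion of member genes targeted by a miRNA
    and identifier canonicalization via alias tables.
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
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
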