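Package: ontotrend
Title: Age Trends of Housekeeping and Integrative Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing age-resolved bulk RNA-seq time courses in which
    the genome is partitioned into a housekeeping (HG) compartment and an
    integrative (IntG) compartment. Provides gene-catalogue construction from
    housekeeping-gene lists, coefficient-of-variation filtering of replicate
    expression values, per-age aggregation of group RNA production with
    confidence intervals, ordinary least-squares age trends with a
    pooled-variance F test for equality of slopes, segmented trend analysis at
    an a-priori breakpoint, HG/IntG production-ratio trajectories across
    ontogenesis stages, gene-block trajectory reports, and a synthetic
    expression-matrix generator with parameter-recovery and test-calibration
    harnesses.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
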