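Package: biodelta
Title: Longitudinal Biomarker Change Networks and Reference-Range Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal analysis of clinical blood-biomarker
    cohorts measured at two time points. Builds biomarker-change (delta)
    correlation networks from pairwise-complete Spearman tests with
    Benjamini-Hochberg false-discovery-rate control, detects biomarker
    communities by hierarchical clustering of the 1 - |rho| distance with an
    adaptive (dynamic) tree cut, screens physiologically implausible values
    by reference-sample percentile limits, tests baseline-to-follow-up change
    in clinically out-of-range subgroups with the Wilcoxon signed-rank test
    (including seasonal adjustment of vitamin D), and tests association
    between intervention choices and biomarker improvement with Monte-Carlo
    chi-square tests. Includes a synthetic-cohort generator with planted
    correlation blocks, panel-based missingness, seasonal offsets and
    intervention effects so that every stage can be validated against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph,
    MASS,
    mclust,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, Clustering, TimeCourse, QualityControl
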