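Package: protScreen
Title: Statistical-Ensemble Detection of Outlier Samples in Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens quantitative proteomics sample matrices for outlier
    samples using a statistical resampling ensemble. A pool of unsupervised
    outlier detectors (local outlier factor, k-nearest-neighbour distances,
    cluster-based local outlier factor, one-class SVM, angle-based and
    empirical-CDF detectors, isolation forests, feature bagging and locally
    selective detector combination) votes over many random subsamples of the
    cohort; candidate outliers are confirmed with a chi-square goodness-of-fit
    test on the vote split. Includes MaxQuant proteinGroups readers, quantile /
    loess / z-score normalization, minimum-value imputation, a
    feature-shuffling simulation harness with Mann-Kendall trend testing for
    detector selection, Grubbs-test baseline QC, a seeded synthetic-data
    generator, and joint decision-boundary visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    limma,
    e1071,
    data.table,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
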