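test_that("Mann-Kendall matches the brute-force oracle on known sequences", {
    r <- mannKendall(1:10)
    expect_equal(r@S, 45L)
    expect_equal(r@varS, 125)
    expect_equal(r@Z, 44 / sqrt(125), tolerance = 1e-12)
    expect_equal(r@pValue, 2 * pnorm(-44 / sqrt(125)), tolerance = 1e-12)

    d <- mannKendall(5:1)
    expect_equal(d@S, -10L)
    expect_equal(d@Z, -9 / sqrt(50 / 3), tolerance = 1e-12)
    expect_equal(d@pValue, 0.0275, tolerance = 1e-3)

    cst <- mannKendall(rep(2, 6))
    expect_equal(cst@S, 0L)
    expect_equal(cst@pValue, 1)

    expect_error(mannKendall(c(1, 2)), "at least 3")
})

test_that("Mann-Kendall equals the pair-loop oracle on random tied sequences", {
    set.seed(41)
    for (i in 1:200) {
        n <- sample(3:12, 1)
        v <- sample(1:3, n, replace = TRUE)
        o <- mkOracle(v)
        r <- mannKendall(v)
        expect_identical(r@S, as.integer(o$S))
        expect_equal(r@varS, o$varS)
        expect_lt(abs(r@pValue - o$p), 1e-12)
    }
})

test_that("Mann-Kendall S is antisymmetric under sequence reversal", {
    set.seed(42)
    for (i in 1:50) {
        v <- rnorm(sample(3:15, 1))
        expect_equal(mannKendall(rev(v))@S, -mannKendall(v)@S)
    }
})

test_that("detection point is the start of the longest stable suffix", {
    # early drop then flat: Seq1 still trends, Seq2 is stable
    dp <- detectionPoint(c(0.5, 0.3, rep(0.02, 8)))
    expect_equal(as.numeric(dp), 0.2)
    tp <- attr(dp, "trendP")
    expect_lt(tp[1], 0.05)
    expect_gte(tp[2], 0.05)

    # all-constant CVs: every suffix stable -> 10%
    expect_equal(as.numeric(detectionPoint(rep(0.1, 10))), 0.1)

    # strictly decreasing: suffixes keep trending until they get too short
    dpd <- detectionPoint(seq(1, 0.1, length.out = 10))
    tpd <- attr(dpd, "trendP")
    firstStable <- which(tpd >= 0.05)[1]
    if (is.na(firstStable)) {
        # only the two-point Seq9 could save it, and it differs -> none
        expect_true(is.na(as.numeric(dpd)))
    } else {
        expect_equal(as.numeric(dpd), firstStable / 10)
    }
    expect_error(detectionPoint(rep(0.1, 7)), "length")
})

test_that("near-equal random groups partition the cohort", {
    ids <- sprintf("H%03d", 1:302)
    g <- makeGroups(ids, k = 10, seed = 3)
    sizes <- lengths(g)
    expect_equal(sort(unname(sizes), decreasing = TRUE),
                 c(31, 31, rep(30, 8)))
    expect_setequal(unlist(g), ids)
    expect_equal(anyDuplicated(unlist(g)), 0L)
    expect_identical(makeGroups(ids, 10, seed = 3), g)
    expect_equal(lengths(makeGroups(letters[1:10], 10, seed = 1)),
                 setNames(rep(1L, 10), as.character(1:10)))
    expect_error(makeGroups(letters[1:5], 10), "cannot split")
})

test_that("feature shuffling preserves per-sample value multisets", {
    ds <- generateDataset(nSamples = 10, nFeatures = 50, outlierFrac = 0,
                          missingFrac = 0, seed = 51)
    m <- datasetMatrix(ds)
    x0 <- intensities(m)
    # proportion 0 -> identity, all labels normal
    p0 <- shuffleFeatures(m, c("S001", "S002"), 0, seed = 1)
    expect_identical(intensities(p0$matrix), x0)
    expect_true(all(p0$truth == "normal"))
    # proportion 1 -> full permutation within the target only
    p1 <- shuffleFeatures(m, "S003", 1, seed = 2)
    x1 <- intensities(p1$matrix)
    expect_equal(sort(x1[, "S003"]), sort(x0[, "S003"]), ignore_attr = TRUE)
    expect_false(identical(x1[, "S003"], x0[, "S003"]))
    expect_identical(x1[, -3], x0[, -3])
    expect_equal(unname(p1$truth["S003"]), "outlier")
    # rounding rule for the shuffled-feature count
    expect_equal(round(0.3 * 6451), 1935)
    p3 <- shuffleFeatures(m, "S004", 0.3, seed = 3)
    expect_equal(sum(x0[, "S004"] != intensities(p3$matrix)[, "S004"]) <=
                 round(0.3 * 50), TRUE)
    expect_error(shuffleFeatures(m, "nope", 0.5), "unknown target")
})

test_that("accuracy grids have the expected shape and limits", {
    ds <- generateDataset(nSamples = 30, nFeatures = 60, outlierFrac = 0,
                          missingFrac = 0, seed = 52)
    clean <- normalizeIntensities(datasetMatrix(ds), "quantile")
    groups <- makeGroups(sampleIds(clean), k = 3, seed = 1)
    cf <- detectorConfig("KNN", list(k = 5L, metric = "euclidean"))
    acc <- evaluateConfig(cf, clean, groups, proportions = c(0.1, 0.5, 1),
                          repeats = 2, seed = 9)
    expect_equal(dim(acc), c(3L, 3L, 2L))
    expect_true(all(acc >= 0 & acc <= 1, na.rm = TRUE))
    # strong perturbation at proportion 1 is caught by a solid KNN config
    expect_gte(mean(acc[3, , ]), 0.95)

    # with proportion ~0 no true outliers exist, so flagged samples all
    # count against accuracy
    acc0 <- evaluateConfig(cf, clean, groups, proportions = 0,
                           repeats = 1, seed = 9)
    n <- ncol(clean)
    cont <- lengths(groups)[1] / n
    expect_lte(mean(acc0), (n - floor(cont * n)) / n)
})

test_that("benchmark summaries compute CV and detection points", {
    ds <- generateDataset(nSamples = 30, nFeatures = 60, outlierFrac = 0,
                          missingFrac = 0, seed = 53)
    clean <- normalizeIntensities(datasetMatrix(ds), "quantile")
    reg <- new("ModelRegistry", name = "tiny", configs = list(
        detectorConfig("KNN", list(k = 5L, metric = "euclidean")),
        detectorConfig("LOF", list(k = 10L, metric = "euclidean"))))
    res <- benchmarkRegistry(reg, clean, k = 2,
                             proportions = seq(0.1, 1, 0.1), repeats = 2,
                             seed = 7)
    expect_equal(length(res), 2L)
    r <- res[[1]]
    expect_equal(length(r@cv), 10L)
    expect_true(all(r@cv >= 0, na.rm = TRUE))
    expect_equal(dim(r@accuracy), c(10L, 2L, 2L))
    # cv of a constant accuracy vector is 0
    constAcc <- array(0.9, c(10, 2, 2))
    s <- summarizeBenchmark("x", constAcc)
    expect_equal(s@cv, rep(0, 10))
    expect_equal(s@detectionPoint, 0.1)
})

test_that("model selection applies balance-point voting and the accuracy gate", {
    # distribution with modal detection point 20% -> criterion 30%
    counts <- c(6, 49, 36, 6, 2, 2, 2, 0, 0)
    dp <- rep(seq(0.1, 0.9, 0.1), counts)
    tab <- data.frame(configId = sprintf("cfg%03d", seq_along(dp)),
                      detectionPoint = dp,
                      accuracyAtPoint = 0.95)
    sel <- selectModels(tab)
    expect_equal(sel$balancePoint, 0.2)
    expect_equal(sel$criterion, 0.3)
    expect_equal(length(sel$selected), 91L)
    expect_equal(sel$summary$count, counts)

    # direct application of the stated rule on a small case
    tab2 <- data.frame(configId = c("a", "b", "c", "d"),
                       detectionPoint = c(0.1, 0.2, 0.2, 0.4),
                       accuracyAtPoint = c(0.95, 0.95, 0.80, 0.95))
    sel2 <- selectModels(tab2)
    expect_equal(sel2$balancePoint, 0.2)
    expect_equal(sel2$criterion, 0.3)
    expect_setequal(sel2$selected, c("a", "b"))   # c fails the gate

    # cap rule: a lone 90% detection point
    tab3 <- data.frame(configId = "z", detectionPoint = 0.9,
                       accuracyAtPoint = 0.99)
    sel3 <- selectModels(tab3)
    expect_equal(sel3$criterion, 1.0)
    expect_equal(sel3$selected, "z")

    # accuracy failure excludes it
    tab3$accuracyAtPoint <- 0.85
    expect_equal(length(selectModels(tab3)$selected), 0L)

    expect_warning(
        none <- selectModels(data.frame(configId = "q",
                                        detectionPoint = NA_real_,
                                        accuracyAtPoint = NA_real_)),
        "empty selection")
    expect_equal(length(none$selected), 0L)
})

test_that("lowering the accuracy threshold never removes a selected config", {
    set.seed(61)
    tab <- data.frame(configId = sprintf("c%02d", 1:40),
                      detectionPoint = sample(seq(0.1, 0.9, 0.1), 40, TRUE),
                      accuracyAtPoint = runif(40, 0.7, 1))
    hi <- selectModels(tab, accuracyThreshold = 0.9)$selected
    lo <- selectModels(tab, accuracyThreshold = 0.8)$selected
    expect_true(all(hi %in% lo))
})

test_that("clean-data curation removes baseline-flagged samples and converges", {
    ds <- generateDataset(nSamples = 24, nFeatures = 300, outlierFrac = 0,
                          missingFrac = 0.1, seed = 55)
    x <- intensities(datasetMatrix(ds))
    # one sample with 90% of its features missing: its id-count is a clear
    # Grubbs outlier
    set.seed(56)
    x[sample(300, 270), 1] <- NA
    m <- IntensityMatrix(x, logTransformed = TRUE)
    clean <- curateClean(m)
    expect_false("S001" %in% sampleIds(clean))
    # idempotent on its own output
    again <- curateClean(clean)
    expect_identical(sampleIds(again), sampleIds(clean))

    # homogeneous cohort: nothing removed
    ds2 <- generateDataset(nSamples = 24, nFeatures = 300, outlierFrac = 0,
                           missingFrac = 0, seed = 57)
    expect_equal(ncol(curateClean(datasetMatrix(ds2))), 24L)
    expect_error(curateClean(datasetMatrix(
        generateDataset(nSamples = 10, seed = 1))), "at least 20")
})
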