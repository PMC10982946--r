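# small fast registry used across ensemble tests
smallRegistry <- function() {
    new("ModelRegistry", name = "small", configs = list(
        detectorConfig("KNN", list(k = 5L, metric = "euclidean")),
        detectorConfig("AvgKNN", list(k = 5L, metric = "manhattan")),
        detectorConfig("LOF", list(k = 10L, metric = "euclidean")),
        detectorConfig("CBLOF", list(nClusters = 4L), seed = 31),
        detectorConfig("OCSVM", list(kernel = "rbf", nu = 0.1))))
}

cloudMatrix <- function(seed = 21) {
    cl <- gaussianCloud(n = 27, d = 30, nOut = 3, shiftSd = 8, seed = seed)
    xt <- t(cl$X)
    rownames(xt) <- paste0("P", seq_len(nrow(xt)))
    m <- IntensityMatrix(xt, logTransformed = TRUE)
    list(m = m, outliers = rownames(cl$X)[cl$outliers])
}

test_that("each round draws ceiling(frac * n) samples and votes conserve", {
    fx <- cloudMatrix()
    votes <- runEnsemble(fx$m, smallRegistry(), nRounds = 6,
                         subsampleFrac = 0.8, seed = 5)
    # n = 30, frac 0.8 -> 24 per round
    expect_true(all(colSums(votes@roundsSeen > 0) <= 6))
    expect_equal(unname(rowSums(votes@roundsSeen) / 6), rep(24, 5))
    expect_equal(votes@outlierVotes + votes@normalVotes,
                 rep(5L, 30))
    expect_true(all(votes@roundsFlagged <= votes@roundsSeen))
})

test_that("one full-cohort round reduces to the single-fit flags per model", {
    fx <- cloudMatrix(22)
    reg <- smallRegistry()
    votes <- runEnsemble(fx$m, reg, nRounds = 1, subsampleFrac = 1,
                         seed = 9)
    X <- t(intensities(fx$m))
    for (ci in seq_along(reg@configs)) {
        fs <- fitScore(reg@configs[[ci]], X)
        expect_equal(unname(votes@roundsFlagged[ci, ] == 1L), fs$flag,
                     info = reg@configs[[ci]]@configId)
    }
})

test_that("planted outliers collect the top outlier votes", {
    ds <- generateDataset(nSamples = 60, nFeatures = 200, outlierFrac = 0.05,
                          magnitude = 6, seed = 21)
    pp <- preprocess(datasetMatrix(ds))
    votes <- suppressMessages(
        runEnsemble(pp, buildSelectedRegistry(), nRounds = 10, seed = 21))
    truth <- names(truthLabels(ds))[truthLabels(ds) == "outlier"]
    top3 <- votes@sampleIds[order(votes@outlierVotes, decreasing = TRUE)][1:3]
    expect_setequal(top3, truth)
})

test_that("the ensemble is deterministic under a fixed master seed", {
    fx <- cloudMatrix(23)
    v1 <- runEnsemble(fx$m, smallRegistry(), nRounds = 4, seed = 3)
    v2 <- runEnsemble(fx$m, smallRegistry(), nRounds = 4, seed = 3)
    expect_identical(v1@roundsFlagged, v2@roundsFlagged)
    expect_identical(v1@meanScores, v2@meanScores)
})

test_that("the candidate pool keeps vote majorities in descending order", {
    fx <- cloudMatrix(24)
    votes <- runEnsemble(fx$m, smallRegistry(), nRounds = 5, seed = 2)
    pool <- candidatePool(votes)
    ov <- setNames(votes@outlierVotes, votes@sampleIds)
    nv <- setNames(votes@normalVotes, votes@sampleIds)
    expect_true(all(ov[pool] > nv[pool]))
    expect_true(all(diff(ov[pool]) <= 0))
    expect_true(all(ov[setdiff(votes@sampleIds, pool)] <=
                    nv[setdiff(votes@sampleIds, pool)]))
})

test_that("majority boundary: 46/45 is a candidate, 45/46 is not", {
    v <- new("VoteTable", sampleIds = c("a", "b"), configIds = "x",
             outlierVotes = c(46L, 45L), normalVotes = c(45L, 46L),
             roundsSeen = matrix(1L, 1, 2), roundsFlagged = matrix(0L, 1, 2),
             meanScores = matrix(0, 1, 2), nModels = 91L, nRounds = 1L,
             subsampleFrac = 1)
    expect_equal(candidatePool(v), "a")
})

test_that("chi-square confirmation reproduces the closed form", {
    res <- chiSquareConfirm(54, 37)
    expect_equal(res$chi2, (54 - 37)^2 / 91)
    expect_equal(res$p_value, 0.0747, tolerance = 1e-3)
    expect_false(res$confirmed)
    # balanced votes
    even <- chiSquareConfirm(20, 20)
    expect_equal(even$chi2, 0)
    expect_equal(even$p_value, 1)
    expect_error(chiSquareConfirm(-1, 5), "non-negative")
    expect_error(chiSquareConfirm(0, 0), "at least one")
})

test_that("chi-square agrees with the generic Pearson GOF routine", {
    grid <- expand.grid(a = seq(0, 200, 8), b = seq(0, 200, 8))
    grid <- grid[grid$a + grid$b > 0, ]
    ours <- chiSquareConfirm(grid$a, grid$b)
    ref <- mapply(function(a, b)
        suppressWarnings(chisq.test(c(a, b), p = c(0.5, 0.5),
                                    correct = FALSE))$p.value,
        grid$a, grid$b)
    expect_lt(max(abs(ours$p_value - ref)), 1e-10)
})

test_that("with 91 votes the smallest confirming outlier count is 55", {
    a <- 46:91
    conf <- chiSquareConfirm(a, 91L - a)
    expect_equal(min(a[conf$confirmed]), 55L)
    # and 54/37 (a majority short of the bound on 91 votes) stays "ns"
    expect_false(chiSquareConfirm(54, 37)$confirmed)
})

test_that("reports assign stars and tolerate empty candidate pools", {
    fx <- cloudMatrix(25)
    votes <- runEnsemble(fx$m, smallRegistry(), nRounds = 6, seed = 4)
    rep <- buildReport(votes)
    tab <- reportTable(rep)
    expect_equal(nrow(tab), 30L)
    cand <- tab[tab$candidate, ]
    expect_true(all(!is.na(cand$p_value)))
    expect_true(all(cand$stars[cand$p_value < 0.001] == "***"))
    expect_true(all(tab$stars[tab$candidate & tab$p_value >= 0.05] == "ns"))
    expect_true(all(is.na(tab$p_value[!tab$candidate])))

    # empty pool: force a vote table with no majorities
    v0 <- new("VoteTable", sampleIds = c("a", "b"), configIds = "x",
              outlierVotes = c(0L, 0L), normalVotes = c(1L, 1L),
              roundsSeen = matrix(1L, 1, 2), roundsFlagged = matrix(0L, 1, 2),
              meanScores = matrix(0, 1, 2), nModels = 1L, nRounds = 1L,
              subsampleFrac = 1)
    rep0 <- buildReport(v0)
    expect_equal(length(confirmedOutliers(rep0)), 0L)
    expect_equal(nrow(reportTable(rep0)), 2L)
})

test_that("stars thresholds follow the 0.001 / 0.01 / 0.05 convention", {
    expect_equal(protScreen:::.stars(c(4e-4, 0.004, 0.04, 0.4)),
                 c("***", "**", "*", "ns"))
})

test_that("group labels trigger fully independent per-group screens", {
    ds1 <- generateDataset(nSamples = 24, nFeatures = 60, outlierFrac = 0.08,
                           missingFrac = 0, seed = 31)
    ds2 <- generateDataset(nSamples = 24, nFeatures = 60, outlierFrac = 0.08,
                           missingFrac = 0, seed = 32)
    x <- cbind(intensities(datasetMatrix(ds1)),
               intensities(datasetMatrix(ds2)))
    colnames(x) <- paste0("S", seq_len(ncol(x)))
    m <- IntensityMatrix(x, logTransformed = TRUE)
    groups <- setNames(rep(c("tumor", "NAT"), each = 24), colnames(x))
    res <- detectOutliers(m, smallRegistry(), groups = groups,
                          nRounds = 4, seed = 8)
    tab <- reportTable(res$report)
    expect_setequal(unique(tab$group), c("tumor", "NAT"))
    expect_equal(sum(tab$group == "tumor"), 24L)
    # per-group votes only ever cover that group's samples
    expect_setequal(res$votes[["tumor"]]@sampleIds,
                    names(groups)[groups == "tumor"])

    # group run equals an isolated run on the same subgroup
    solo <- detectOutliers(
        IntensityMatrix(x[, groups == "tumor"], logTransformed = TRUE),
        smallRegistry(), nRounds = 4, seed = 8)
    expect_equal(res$votes[["tumor"]]@outlierVotes,
                 solo$votes[["all"]]@outlierVotes)
})

test_that("reports serialize to TSV and JSON", {
    fx <- cloudMatrix(26)
    votes <- runEnsemble(fx$m, smallRegistry(), nRounds = 3, seed = 1)
    rep <- buildReport(votes)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    js <- withr::local_tempfile(fileext = ".json")
    writeReport(rep, tsv)
    writeReport(rep, js, "json")
    back <- read.delim(tsv)
    expect_equal(nrow(back), 30L)
    parsed <- jsonlite::read_json(js)
    expect_equal(parsed$n_models, 5L)
})
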