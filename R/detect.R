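#' End-to-end outlier-sample detection
#'
#' Runs the full screening pipeline: preprocessing (missing-value filter,
#' minimum imputation, normalization — skipped with `preprocessed = TRUE`),
#' the multi-round subsample voting ensemble over the detector registry, and
#' chi-square confirmation of the candidate pool.
#'
#' When group labels are supplied (e.g. tumor versus normal adjacent
#' tissue), every group is screened fully independently — subsampling,
#' voting and confirmation never mix groups — and the per-group reports are
#' concatenated.
#'
#' @param m an [IntensityMatrix-class].
#' @param registry a [ModelRegistry-class]; defaults to the shipped
#'   selection of 91 configurations.
#' @param groups optional per-sample labels: a named character vector (names
#'   = sample ids) or a vector aligned with the columns of `m`.
#' @param nRounds,subsampleFrac,seed see [runEnsemble()].
#' @param alpha confirmation significance level.
#' @param preprocessed set TRUE when `m` is already filtered, imputed and
#'   normalized.
#' @param maxMissingFrac,method passed to [preprocess()].
#' @return list with `report` (an [OutlierReport-class] over all groups) and
#'   `votes` (a named list of [VoteTable-class], one per group).
#' @examples
#' ds <- generateDataset(nSamples = 40, nFeatures = 100, seed = 7)
#' res <- detectOutliers(datasetMatrix(ds), nRounds = 5, seed = 7)
#' res$report
#' @export
detectOutliers <- function(m, registry = buildSelectedRegistry(),
                           groups = NULL, nRounds = 100L,
                           subsampleFrac = 0.8, alpha = 0.05, seed = 1L,
                           preprocessed = FALSE, maxMissingFrac = 0.75,
                           method = "quantile") {
    if (is.null(groups)) {
        groups <- setNames(rep("all", ncol(m)), sampleIds(m))
    } else if (is.null(names(groups))) {
        if (length(groups) != ncol(m))
            stop("unnamed 'groups' must have one label per sample")
        groups <- setNames(as.character(groups), sampleIds(m))
    } else {
        missing <- setdiff(sampleIds(m), names(groups))
        if (length(missing))
            stop("no group label for sample(s): ",
                 paste(missing, collapse = ", "))
        groups <- groups[sampleIds(m)]
    }
    lev <- unique(groups)
    votesList <- list()
    tables <- list()
    for (gi in seq_along(lev)) {
        g <- lev[gi]
        sub <- IntensityMatrix(
            intensities(m)[, groups == g, drop = FALSE],
            isLogTransformed(m))
        if (!preprocessed)
            sub <- preprocess(sub, maxMissingFrac = maxMissingFrac,
                              method = method)
        votes <- runEnsemble(sub, registry, nRounds, subsampleFrac,
                             seed = seed + 131L * (gi - 1L))
        votesList[[g]] <- votes
        tables[[g]] <- reportTable(buildReport(votes, alpha, group = g))
    }
    res <- do.call(rbind, tables)
    rownames(res) <- NULL
    report <- new("OutlierReport", results = res, alpha = alpha,
                  nModels = length(registry))
    list(report = report, votes = votesList)
}
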