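#' Multi-round subsample voting over a detector registry
#'
#' Each round draws `ceiling(subsampleFrac * n)` samples without replacement
#' (seeded), fits every registry configuration on the subset and flags
#' outliers within it.  Per configuration, a sample's vote is "outlier" when
#' it was flagged in more than half of the rounds whose subset contained it
#' (ties count as normal), so per-sample vote totals equal the number of
#' configurations.  Configurations infeasible on a given subset (e.g. a
#' neighbour count exceeding the subset size) are skipped for that round and
#' reported once via `message()`.
#'
#' @param m a fully imputed/normalized [IntensityMatrix-class].
#' @param registry a [ModelRegistry-class]; default is the shipped selection
#'   of 91 configurations.
#' @param nRounds number of resampling rounds (>= 1).
#' @param subsampleFrac fraction of samples drawn per round, in (0, 1].
#' @param seed master seed; per-round draws use fixed offsets so adding
#'   rounds never perturbs earlier rounds.
#' @return a [VoteTable-class].
#' @export
runEnsemble <- function(m, registry = buildSelectedRegistry(),
                        nRounds = 100L, subsampleFrac = 0.8, seed = 1L) {
    stopifnot(nRounds >= 1L, subsampleFrac > 0, subsampleFrac <= 1)
    X <- t(intensities(m))
    if (anyNA(X))
        stop("matrix has missing values; impute before running the ensemble")
    n <- nrow(X)
    nSub <- as.integer(ceiling(subsampleFrac * n))
    nCfg <- length(registry)
    if (nCfg == 0L) stop("registry has no configurations")
    ids <- .rowIds(X)
    cfgIds <- configIds(registry)
    seen <- flagged <- matrix(0L, nCfg, n, dimnames = list(cfgIds, ids))
    scoreSum <- matrix(0, nCfg, n, dimnames = list(cfgIds, ids))
    skipped <- integer(nCfg)
    for (r in seq_len(nRounds)) {
        sub <- .withSeed(seed + 2L * r, sort(sample.int(n, nSub)))
        Xs <- X[sub, , drop = FALSE]
        cache <- .makeScoreCache(Xs)
        for (ci in seq_len(nCfg)) {
            cf <- registry@configs[[ci]]
            if (nSub < max(5L, .neededSamples(cf))) {
                skipped[ci] <- skipped[ci] + 1L
                next
            }
            score <- tryCatch(.scoreConfig(cf, Xs, cache),
                              protScreen_infeasible = function(e) NULL,
                              error = function(e) NULL)
            if (is.null(score)) {
                skipped[ci] <- skipped[ci] + 1L
                next
            }
            fl <- .flagScores(score, cf@contamination)
            seen[ci, sub] <- seen[ci, sub] + 1L
            flagged[ci, sub] <- flagged[ci, sub] + as.integer(fl)
            scoreSum[ci, sub] <- scoreSum[ci, sub] + score
        }
    }
    if (any(colSums(seen) == 0L))
        stop("some samples were never drawn into any subset; ",
             "raise nRounds or subsampleFrac")
    if (any(skipped > 0L))
        message(sum(skipped > 0L), " config(s) skipped in some rounds ",
                "(infeasible on the subset size)")
    votes <- flagged > seen / 2                 # ties count as normal
    ov <- as.integer(colSums(votes))
    meanScores <- scoreSum / seen
    meanScores[seen == 0L] <- NA_real_
    new("VoteTable", sampleIds = ids, configIds = cfgIds,
        outlierVotes = ov, normalVotes = as.integer(nCfg - ov),
        roundsSeen = seen, roundsFlagged = flagged, meanScores = meanScores,
        nModels = nCfg, nRounds = as.integer(nRounds),
        subsampleFrac = subsampleFrac)
}

setMethod("show", "VoteTable", function(object) {
    cat(sprintf(
        "VoteTable: %d samples, %d models, %d rounds (subsample %.0f%%)\n",
        length(object@sampleIds), object@nModels, object@nRounds,
        100 * object@subsampleFrac))
    nc <- sum(object@outlierVotes > object@normalVotes)
    cat("  candidate outliers (majority votes): ", nc, "\n", sep = "")
})

#' Candidate outlier pool
#'
#' Samples with a strict majority of outlier votes, in descending
#' outlier-vote order.  Samples primarily voted normal are excluded from
#' chi-square confirmation.
#'
#' @param votes a [VoteTable-class].
#' @return character vector of sample ids (possibly empty).
#' @export
candidatePool <- function(votes) {
    cand <- votes@outlierVotes > votes@normalVotes
    ids <- votes@sampleIds[cand]
    ids[order(votes@outlierVotes[cand], decreasing = TRUE)]
}

#' Chi-square confirmation of a vote split
#'
#' One-degree-of-freedom goodness-of-fit of the outlier/normal vote split
#' against equal expected counts, without continuity correction:
#' `chi2 = (a - b)^2 / (a + b)` with an upper-tail chi-square p-value.  A
#' candidate is confirmed when `p < alpha` and the outlier votes hold the
#' majority.  Vectorized over vote pairs.
#'
#' @param outlierVotes,normalVotes non-negative integer vote counts
#'   (`outlierVotes + normalVotes >= 1`).
#' @param alpha significance level (default 0.05, i.e. a 95% confidence
#'   level).
#' @return data.frame with columns `chi2`, `p_value`, `confirmed`.
#' @examples
#' chiSquareConfirm(54, 37)   # p ~ 0.075: not confirmed
#' @export
chiSquareConfirm <- function(outlierVotes, normalVotes, alpha = 0.05) {
    a <- outlierVotes; b <- normalVotes
    if (any(a < 0) || any(b < 0)) stop("vote counts must be non-negative")
    if (any(a + b < 1)) stop("need at least one vote")
    chi2 <- (a - b)^2 / (a + b)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    data.frame(chi2 = chi2, p_value = p, confirmed = p < alpha & a > b)
}

.stars <- function(p) {
    ifelse(is.na(p), NA_character_,
           ifelse(p < 0.001, "***",
                  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Assemble the outlier report
#'
#' One row per sample: vote counts for everyone, plus the chi-square
#' statistic, p-value, confirmed flag and significance stars for candidates
#' (majority outlier votes).  An empty candidate pool yields a valid report
#' with no confirmed outliers.
#'
#' @param votes a [VoteTable-class].
#' @param alpha significance level for confirmation.
#' @param group group label recorded on every row (default `"all"`).
#' @return an [OutlierReport-class].
#' @export
buildReport <- function(votes, alpha = 0.05, group = "all") {
    ov <- votes@outlierVotes
    nv <- votes@normalVotes
    cand <- ov > nv
    res <- data.frame(sample_id = votes@sampleIds, group = group,
                      outlier_votes = ov, normal_votes = nv,
                      candidate = cand, chi2 = NA_real_,
                      p_value = NA_real_, confirmed = FALSE,
                      stars = NA_character_, stringsAsFactors = FALSE)
    if (any(cand)) {
        conf <- chiSquareConfirm(ov[cand], nv[cand], alpha)
        res$chi2[cand] <- conf$chi2
        res$p_value[cand] <- conf$p_value
        res$confirmed[cand] <- conf$confirmed
        res$stars[cand] <- .stars(conf$p_value)
    }
    res <- res[order(res$candidate, res$outlier_votes,
                     decreasing = TRUE), , drop = FALSE]
    rownames(res) <- NULL
    new("OutlierReport", results = res, alpha = alpha,
        nModels = votes@nModels)
}

setMethod("show", "OutlierReport", function(object) {
    res <- object@results
    cat(sprintf("OutlierReport: %d samples, %d models, alpha = %g\n",
                nrow(res), object@nModels, object@alpha))
    conf <- res[res$confirmed, , drop = FALSE]
    cat("  confirmed outliers: ", nrow(conf), "\n", sep = "")
    if (nrow(conf)) {
        print(conf[, c("sample_id", "group", "outlier_votes",
                       "normal_votes", "p_value", "stars")],
              row.names = FALSE)
    }
})

#' Report accessors
#'
#' `reportTable()` returns the full per-sample table,
#' `confirmedOutliers()` the confirmed outlier sample ids.
#'
#' @param report an [OutlierReport-class].
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
reportTable <- function(report) report@results

#' @rdname report-accessors
#' @export
confirmedOutliers <- function(report)
    report@results$sample_id[report@results$confirmed]

#' Write an outlier report to disk
#'
#' @param report an [OutlierReport-class].
#' @param path output path; format follows the extension unless given.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
    format <- if (missing(format) && grepl("\\.json$", path)) "json"
              else match.arg(format)
    if (format == "tsv") {
        utils::write.table(report@results, path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    } else {
        jsonlite::write_json(
            list(alpha = report@alpha, n_models = report@nModels,
                 results = report@results),
            path, auto_unbox = TRUE, digits = NA, na = "null")
    }
    invisible(path)
}
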