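#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test: `S` is the sum of pairwise value signs,
#' its variance carries the standard tie correction, and the normal deviate
#' is continuity-corrected (`Z = (S -/+ 1)/sqrt(varS)`, 0 when `S = 0`) with
#' a two-sided p-value.  An all-tied sequence gives `S = 0`, `p = 1`.
#'
#' @param values ordered numeric sequence, length >= 3.
#' @return a [TrendResult-class].
#' @export
mannKendall <- function(values) {
    n <- length(values)
    if (n < 3L) stop("Mann-Kendall test needs at least 3 values")
    S <- 0L
    for (i in seq_len(n - 1L))
        S <- S + sum(sign(values[(i + 1L):n] - values[i]))
    S <- as.integer(S)
    ties <- table(values)
    t <- as.numeric(ties[ties > 1L])
    varS <- (n * (n - 1) * (2 * n + 5) -
             sum(t * (t - 1) * (2 * t + 5))) / 18
    if (S == 0L) {
        Z <- 0
    } else if (varS <= 0) {
        Z <- 0
    } else {
        Z <- (S - sign(S)) / sqrt(varS)
    }
    p <- 2 * stats::pnorm(-abs(Z))
    new("TrendResult", S = S, varS = varS, Z = Z, pValue = p,
        n = as.integer(n))
}

setMethod("show", "TrendResult", function(object) {
    cat(sprintf("Mann-Kendall: S = %d, varS = %.4g, Z = %.4f, p = %.4g (n = %d)\n",
                object@S, object@varS, object@Z, object@pValue, object@n))
})

#' Detection point of a CV-versus-shuffle-proportion curve
#'
#' The shuffle-proportion axis (10%..100%) is cut into nine suffixes
#' (Seq1 = 10-100% ... Seq9 = 90-100%).  The Mann-Kendall test is applied to
#' each suffix with at least 3 points; the detection point is the smallest
#' starting proportion whose suffix shows no significant trend (two-sided
#' `p >= alpha`), i.e. the start of the longest trend-stable suffix.  Seq9
#' has only two points, so it is assessed descriptively: stable when its two
#' CVs differ by less than `seq9Tol`.
#'
#' @param cvByProportion exactly one CV per proportion 10%..100% (length 10).
#' @param proportions the proportion grid (default `seq(0.1, 1, 0.1)`).
#' @param alpha trend-significance level (default 0.05).
#' @param seq9Tol tolerance used for the two-point Seq9 (default 1e-6).
#' @return the detection point as a proportion (`NA` if no suffix is
#'   stable), with the per-suffix Mann-Kendall p-values in attribute
#'   `"trendP"`.
#' @export
detectionPoint <- function(cvByProportion, proportions = seq(0.1, 1, 0.1),
                           alpha = 0.05, seq9Tol = 1e-6) {
    if (length(cvByProportion) != length(proportions))
        stop("need exactly one CV per proportion (length ",
             length(proportions), ")")
    nSeq <- length(proportions) - 1L
    trendP <- rep(NA_real_, nSeq)
    stable <- logical(nSeq)
    for (s in seq_len(nSeq)) {
        suffix <- cvByProportion[s:length(cvByProportion)]
        if (length(suffix) >= 3L) {
            trendP[s] <- mannKendall(suffix)@pValue
            stable[s] <- trendP[s] >= alpha
        } else {
            stable[s] <- abs(diff(suffix)) < seq9Tol
        }
    }
    point <- if (any(stable)) proportions[which(stable)[1L]] else NA_real_
    structure(point, trendP = trendP)
}

#' Remove baseline-flagged samples before simulation
#'
#' Curates a clean benchmark cohort: samples flagged by the iterative Grubbs
#' test on per-sample identification counts or on mean inter-sample
#' correlation (see [qcStats()] and [grubbsTest()]) are removed.
#'
#' @param m an [IntensityMatrix-class] with at least 20 samples.
#' @param alpha Grubbs significance level (default 0.05).
#' @return the curated [IntensityMatrix-class].
#' @export
curateClean <- function(m, alpha = 0.05) {
    if (ncol(m) < 20L) stop("clean-data curation needs at least 20 samples")
    qc <- qcStats(m)
    bad <- logical(ncol(m))
    g1 <- suppressWarnings(grubbsTest(qc$id_count, alpha = alpha))
    if (nrow(g1)) bad[g1$index] <- TRUE
    ok <- !is.na(qc$mean_correlation)
    g2 <- suppressWarnings(grubbsTest(qc$mean_correlation[ok],
                                      alpha = alpha))
    if (nrow(g2)) bad[which(ok)[g2$index]] <- TRUE
    x <- intensities(m)
    IntensityMatrix(x[, !bad, drop = FALSE], isLogTransformed(m))
}

#' Partition samples into near-equal random groups
#'
#' @param sampleIds character vector of sample ids.
#' @param k number of groups (default 10).
#' @param seed shuffle seed.
#' @return named list of `k` disjoint, exhaustive id vectors whose sizes
#'   differ by at most 1.
#' @export
makeGroups <- function(sampleIds, k = 10L, seed = 1L) {
    n <- length(sampleIds)
    if (n < k) stop("cannot split ", n, " samples into ", k, " groups")
    perm <- .withSeed(seed, sample(sampleIds))
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    split(perm, rep(seq_len(k), sizes))
}

#' Perturb samples by within-sample feature shuffling
#'
#' For each target sample independently, `round(proportion * F)` features
#' are chosen at random and their values are permuted among themselves
#' within that sample, destroying feature identity while preserving the
#' sample's value multiset.  Non-target samples are untouched.
#'
#' @param m an [IntensityMatrix-class].
#' @param targetSamples sample ids to perturb.
#' @param proportion fraction of features to shuffle, in \[0, 1\].
#' @param seed RNG seed.
#' @param crossSample alternative mode: the chosen features of each target
#'   sample are replaced by the values of a random other sample (per
#'   feature), instead of being permuted within the sample.
#' @return list with `matrix` (the perturbed [IntensityMatrix-class]) and
#'   `truth` (per-sample `"normal"`/`"outlier"` labels; targets are
#'   outliers only when at least one feature was shuffled).
#' @export
shuffleFeatures <- function(m, targetSamples, proportion, seed = 1L,
                            crossSample = FALSE) {
    stopifnot(proportion >= 0, proportion <= 1)
    x <- intensities(m)
    targets <- match(targetSamples, colnames(x))
    if (anyNA(targets)) stop("unknown target sample(s)")
    nShuf <- round(proportion * nrow(x))
    truth <- setNames(rep("normal", ncol(x)), colnames(x))
    if (nShuf > 0L && length(targets)) {
        .withSeed(seed, for (s in targets) {
            feats <- sample.int(nrow(x), nShuf)
            if (crossSample) {
                donors <- sample(setdiff(seq_len(ncol(x)), s),
                                 nShuf, replace = TRUE)
                x[feats, s] <- x[cbind(feats, donors)]
            } else {
                x[feats, s] <- x[feats, s][sample.int(nShuf)]
            }
        })
        truth[targets] <- "outlier"
    }
    list(matrix = IntensityMatrix(x, isLogTransformed(m)), truth = truth)
}

#' Accuracy grid of one configuration over the shuffle-proportion gradient
#'
#' For each proportion x group x repeat cell, the chosen group's samples are
#' feature-shuffled at that proportion, the configuration is fitted on the
#' full (clean + perturbed) matrix with contamination set to the true group
#' fraction, and accuracy is the fraction of samples whose flag matches the
#' truth labels.
#'
#' @param config a [DetectorConfig-class].
#' @param cleanMatrix curated, fully observed [IntensityMatrix-class].
#' @param groups list of sample-id groups (see [makeGroups()]).
#' @param proportions shuffle proportions (default 10%..100%).
#' @param repeats repeats per proportion x group cell (default 10).
#' @param seed master seed.
#' @return 3-d accuracy array `proportion x group x repeat` (NA where the
#'   configuration was infeasible).
#' @export
evaluateConfig <- function(config, cleanMatrix, groups,
                           proportions = seq(0.1, 1, 0.1), repeats = 10L,
                           seed = 1L) {
    n <- ncol(cleanMatrix)
    acc <- array(NA_real_,
                 dim = c(length(proportions), length(groups), repeats),
                 dimnames = list(paste0(round(100 * proportions), "%"),
                                 names(groups), NULL))
    for (pi in seq_along(proportions)) {
        for (gi in seq_along(groups)) {
            cont <- min(max(length(groups[[gi]]) / n, 0.01), 0.49)
            cf <- config
            cf@contamination <- cont
            for (r in seq_len(repeats)) {
                cellSeed <- seed + 97L * pi + 17L * gi + 1009L * r
                pert <- shuffleFeatures(cleanMatrix, groups[[gi]],
                                        proportions[pi], cellSeed)
                fs <- tryCatch(fitScore(cf, pert$matrix),
                               protScreen_infeasible = function(e) NULL)
                if (is.null(fs)) next
                truthFlag <- pert$truth[fs$sample_id] == "outlier"
                acc[pi, gi, r] <- mean(fs$flag == truthFlag)
            }
        }
    }
    acc
}

#' Summarize an accuracy grid into a benchmark result
#'
#' @param configId configuration id.
#' @param accuracy array from [evaluateConfig()].
#' @param proportions shuffle proportions of the grid's first dimension.
#' @param alpha,seq9Tol passed to [detectionPoint()].
#' @return a [BenchmarkResult-class] with per-proportion mean accuracy,
#'   CV (sd/mean over all group x repeat cells) and the detection point.
#' @export
summarizeBenchmark <- function(configId, accuracy,
                               proportions = seq(0.1, 1, 0.1),
                               alpha = 0.05, seq9Tol = 1e-6) {
    meanAcc <- apply(accuracy, 1L, mean, na.rm = TRUE)
    cv <- apply(accuracy, 1L, function(a) {
        m <- mean(a, na.rm = TRUE)
        if (!is.finite(m) || m == 0) return(NA_real_)
        stats::sd(a, na.rm = TRUE) / m
    })
    dp <- if (anyNA(cv))
        structure(NA_real_, trendP = rep(NA_real_,
                                         length(proportions) - 1L))
    else detectionPoint(cv, proportions, alpha, seq9Tol)
    new("BenchmarkResult", configId = configId, accuracy = accuracy,
        proportions = proportions, meanAccuracy = unname(meanAcc),
        cv = unname(cv), detectionPoint = as.numeric(dp),
        trendP = attr(dp, "trendP"))
}

setMethod("show", "BenchmarkResult", function(object) {
    cat(sprintf("BenchmarkResult %s: detection point %s\n", object@configId,
                if (is.na(object@detectionPoint)) "none"
                else sprintf("%.0f%%", 100 * object@detectionPoint)))
    cat("  mean accuracy: ",
        paste(sprintf("%.2f", object@meanAccuracy), collapse = " "), "\n",
        sep = "")
})

#' Run the simulation benchmark for every configuration of a registry
#'
#' @param registry a [ModelRegistry-class].
#' @param cleanMatrix curated clean [IntensityMatrix-class] (see
#'   [curateClean()]).
#' @param k number of sample groups.
#' @param proportions,repeats,seed,alpha,seq9Tol see [evaluateConfig()] and
#'   [summarizeBenchmark()].
#' @return named list of [BenchmarkResult-class], one per configuration.
#' @export
benchmarkRegistry <- function(registry, cleanMatrix, k = 10L,
                              proportions = seq(0.1, 1, 0.1), repeats = 10L,
                              seed = 1L, alpha = 0.05, seq9Tol = 1e-6) {
    groups <- makeGroups(sampleIds(cleanMatrix), k, seed)
    out <- lapply(registry@configs, function(cf) {
        acc <- evaluateConfig(cf, cleanMatrix, groups, proportions,
                              repeats, seed)
        summarizeBenchmark(cf@configId, acc, proportions, alpha, seq9Tol)
    })
    names(out) <- configIds(registry)
    out
}

#' Select detector configurations from benchmark results
#'
#' The balance point is the modal detection point over all configurations
#' (ties resolved toward the smaller proportion); the selection criterion is
#' the next 10% node above it (capped at 100%).  A configuration is selected
#' when its detection point is at or below the criterion and its mean
#' accuracy at the detection point strictly exceeds `accuracyThreshold`.
#'
#' @param results either a list of [BenchmarkResult-class] objects or a
#'   data.frame with columns `configId`, `detectionPoint`,
#'   `accuracyAtPoint`.
#' @param accuracyThreshold accuracy gate (default 0.90, i.e. "over 90%").
#' @return list with `selected` (config ids), `balancePoint`, `criterion`
#'   and `summary` (a per-proportion count of detection points, 10%..90%).
#' @export
selectModels <- function(results, accuracyThreshold = 0.90) {
    if (is.data.frame(results)) {
        tab <- results
    } else {
        tab <- data.frame(
            configId = vapply(results, function(r) r@configId, character(1)),
            detectionPoint = vapply(results, function(r) r@detectionPoint,
                                    numeric(1)),
            accuracyAtPoint = vapply(results, function(r) {
                if (is.na(r@detectionPoint)) return(NA_real_)
                r@meanAccuracy[match(r@detectionPoint, r@proportions)]
            }, numeric(1)))
    }
    grid <- seq(0.1, 0.9, 0.1)
    dp <- tab$detectionPoint
    counts <- vapply(grid, function(p)
        sum(!is.na(dp) & abs(dp - p) < 1e-9), integer(1))
    if (all(is.na(dp))) {
        warning("no configuration has a detection point; empty selection")
        return(list(selected = character(), balancePoint = NA_real_,
                    criterion = NA_real_,
                    summary = data.frame(proportion = grid, count = counts)))
    }
    balance <- grid[which.max(counts)]        # which.max takes the smaller tie
    criterion <- min(balance + 0.1, 1.0)
    sel <- !is.na(dp) & dp <= criterion + 1e-9 &
        !is.na(tab$accuracyAtPoint) & tab$accuracyAtPoint > accuracyThreshold
    list(selected = tab$configId[sel], balancePoint = balance,
         criterion = criterion,
         summary = data.frame(proportion = grid, count = counts))
}
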