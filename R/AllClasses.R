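#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
NULL

#' Container for a feature-by-sample intensity matrix
#'
#' `IntensityMatrix` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one assay, `"intensity"`, a feature-by-sample numeric matrix in which
#' `NA` marks missing (unquantified) entries.  Whether the values are on log2
#' scale is recorded in the object metadata and queried with
#' [isLogTransformed()].
#'
#' Observed entries must be finite; row (feature) and column (sample) names
#' must be unique.
#'
#' @seealso [IntensityMatrix()], [readMaxQuant()], [readIntensityMatrix()]
#' @aliases IntensityMatrix-class
#' @exportClass IntensityMatrix
setClass("IntensityMatrix", contains = "SummarizedExperiment")

setValidity("IntensityMatrix", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        x <- assay(object, "intensity")
        if (!is.numeric(x))
            msg <- c(msg, "intensity assay must be numeric")
        else if (any(!is.finite(x[!is.na(x)])))
            msg <- c(msg, "observed intensities must be finite")
        if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
            msg <- c(msg, "feature ids must be present and unique")
        if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
            msg <- c(msg, "sample ids must be present and unique")
    }
    lt <- metadata(object)$logTransformed
    if (is.null(lt) || !is.logical(lt) || length(lt) != 1L || is.na(lt))
        msg <- c(msg, "metadata flag 'logTransformed' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' A single unsupervised detector configuration
#'
#' One member of the detector pool: an algorithm family, its hyperparameters,
#' the contamination fraction used to turn scores into outlier flags, and a
#' seed fixing any internal randomness.
#'
#' @slot family one of `"LOF"`, `"KNN"`, `"AvgKNN"`, `"CBLOF"`, `"OCSVM"`,
#'   `"ABOD"`, `"ECOD"`, `"IForest"`, `"FeatureBagging"`, `"LSCP"`.
#' @slot hyperparameters named list, validated per family.
#' @slot contamination assumed outlier fraction in (0, 0.5); sets the score
#'   quantile above which samples are flagged.
#' @slot seed integer seed for stochastic detectors.
#' @slot configId unique identifier within a registry.
#' @aliases DetectorConfig-class
#' @exportClass DetectorConfig
setClass("DetectorConfig", representation(
    family = "character",
    hyperparameters = "list",
    contamination = "numeric",
    seed = "integer",
    configId = "character"
))

.DETECTOR_FAMILIES <- c("LOF", "KNN", "AvgKNN", "CBLOF", "OCSVM", "ABOD",
                        "ECOD", "IForest", "FeatureBagging", "LSCP")
.KNN_METRICS <- c("euclidean", "manhattan", "chebyshev")
.OCSVM_KERNELS <- c("rbf", "sigmoid", "poly")

setValidity("DetectorConfig", function(object) {
    msg <- character()
    if (length(object@family) != 1L || !object@family %in% .DETECTOR_FAMILIES)
        msg <- c(msg, paste0("family must be one of: ",
                             paste(.DETECTOR_FAMILIES, collapse = ", ")))
    if (length(object@contamination) != 1L ||
        object@contamination <= 0 || object@contamination >= 0.5)
        msg <- c(msg, "contamination must lie in (0, 0.5)")
    if (length(object@configId) != 1L || !nzchar(object@configId))
        msg <- c(msg, "configId must be a non-empty string")
    h <- object@hyperparameters
    fam <- object@family
    if (length(msg) == 0L) {
        if (fam %in% c("LOF", "KNN", "AvgKNN", "ABOD")) {
            if (is.null(h$k) || h$k < 1)
                msg <- c(msg, "neighbour count k must be >= 1")
            if (fam != "ABOD" &&
                (is.null(h$metric) || !h$metric %in% .KNN_METRICS))
                msg <- c(msg, paste0("metric must be one of: ",
                                     paste(.KNN_METRICS, collapse = ", ")))
        } else if (fam == "CBLOF") {
            if (is.null(h$nClusters) || h$nClusters < 2)
                msg <- c(msg, "nClusters must be >= 2")
        } else if (fam == "OCSVM") {
            if (is.null(h$kernel) || !h$kernel %in% .OCSVM_KERNELS)
                msg <- c(msg, paste0("kernel must be one of: ",
                                     paste(.OCSVM_KERNELS, collapse = ", ")))
            if (is.null(h$nu) || h$nu <= 0 || h$nu >= 1)
                msg <- c(msg, "nu must lie in (0, 1)")
        } else if (fam == "IForest") {
            if (is.null(h$nTrees) || h$nTrees < 1)
                msg <- c(msg, "nTrees must be >= 1")
        } else if (fam == "FeatureBagging") {
            if (is.null(h$nEstimators) || h$nEstimators < 1)
                msg <- c(msg, "nEstimators must be >= 1")
        } else if (fam == "LSCP") {
            if (is.null(h$poolSize) || h$poolSize < 2)
                msg <- c(msg, "poolSize must be >= 2")
        }
    }
    if (length(msg)) msg else TRUE
})

#' An ordered pool of detector configurations
#'
#' @slot configs list of [DetectorConfig-class] objects with unique ids.
#' @slot name registry label.
#' @aliases ModelRegistry-class
#' @exportClass ModelRegistry
setClass("ModelRegistry", representation(
    configs = "list",
    name = "character"
))

setValidity("ModelRegistry", function(object) {
    ok <- vapply(object@configs, is, logical(1), class2 = "DetectorConfig")
    if (!all(ok))
        return("all registry members must be DetectorConfig objects")
    ids <- vapply(object@configs, function(cf) cf@configId, character(1))
    if (anyDuplicated(ids))
        return("configIds must be unique within a registry")
    TRUE
})

#' Per-sample vote counts from the resampling ensemble
#'
#' One vote per detector configuration and sample: a configuration votes
#' "outlier" for a sample when it flagged the sample in more than half of the
#' resampling rounds whose subset contained it.  `outlierVotes + normalVotes`
#' equals the number of configurations for every sample.
#'
#' @slot sampleIds sample identifiers (ensemble order).
#' @slot configIds detector configuration identifiers.
#' @slot outlierVotes,normalVotes integer vote counts per sample.
#' @slot roundsSeen,roundsFlagged config-by-sample integer matrices of rounds
#'   in which each sample was subsampled / flagged.
#' @slot meanScores config-by-sample matrix of mean raw outlier scores over
#'   the rounds in which the pair was observed (`NA` if never observed).
#' @slot nModels,nRounds,subsampleFrac ensemble settings.
#' @aliases VoteTable-class
#' @exportClass VoteTable
setClass("VoteTable", representation(
    sampleIds = "character",
    configIds = "character",
    outlierVotes = "integer",
    normalVotes = "integer",
    roundsSeen = "matrix",
    roundsFlagged = "matrix",
    meanScores = "matrix",
    nModels = "integer",
    nRounds = "integer",
    subsampleFrac = "numeric"
))

setValidity("VoteTable", function(object) {
    n <- length(object@sampleIds)
    if (length(object@outlierVotes) != n || length(object@normalVotes) != n)
        return("vote vectors must match the number of samples")
    if (any(object@outlierVotes + object@normalVotes != object@nModels))
        return("outlierVotes + normalVotes must equal nModels for every sample")
    if (any(object@roundsFlagged > object@roundsSeen))
        return("roundsFlagged cannot exceed roundsSeen")
    if (any(object@roundsSeen > object@nRounds))
        return("roundsSeen cannot exceed nRounds")
    TRUE
})

#' Confirmed-outlier report
#'
#' One row per sample with vote counts and, for candidates (majority outlier
#' votes), the chi-square confirmation statistic, p-value, confirmed flag and
#' significance stars (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns`).
#'
#' @slot results data.frame with columns `sample_id`, `group`,
#'   `outlier_votes`, `normal_votes`, `candidate`, `chi2`, `p_value`,
#'   `confirmed`, `stars`.
#' @slot alpha significance level used for confirmation.
#' @slot nModels ensemble size the votes are out of.
#' @aliases OutlierReport-class
#' @exportClass OutlierReport
setClass("OutlierReport", representation(
    results = "data.frame",
    alpha = "numeric",
    nModels = "integer"
))

#' Mann-Kendall trend test result
#'
#' @slot S integer Mann-Kendall score (sum of pairwise signs).
#' @slot varS tie-corrected variance of S.
#' @slot Z continuity-corrected normal deviate (0 when S = 0).
#' @slot pValue two-sided normal p-value.
#' @slot n sequence length.
#' @aliases TrendResult-class
#' @exportClass TrendResult
setClass("TrendResult", representation(
    S = "integer", varS = "numeric", Z = "numeric",
    pValue = "numeric", n = "integer"
))

#' Simulation benchmark result for one detector configuration
#'
#' @slot configId detector configuration id.
#' @slot accuracy 3-d array `proportion x group x repeat` of detection
#'   accuracies on feature-shuffled data.
#' @slot proportions shuffle proportions (columns of the accuracy grid).
#' @slot meanAccuracy,cv per-proportion mean accuracy and coefficient of
#'   variation (sd/mean) over all group-by-repeat cells.
#' @slot detectionPoint smallest shuffle proportion from which the CV curve is
#'   trend-stable (NA if none).
#' @slot trendP per-suffix Mann-Kendall p-values (Seq1..Seq9).
#' @aliases BenchmarkResult-class
#' @exportClass BenchmarkResult
setClass("BenchmarkResult", representation(
    configId = "character",
    accuracy = "array",
    proportions = "numeric",
    meanAccuracy = "numeric",
    cv = "numeric",
    detectionPoint = "numeric",
    trendP = "numeric"
))
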