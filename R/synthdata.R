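#' Synthetic proteomics dataset with planted outlier samples
#'
#' @slot matrix the generated [IntensityMatrix-class] (log2 scale).
#' @slot truth per-sample labels, `"normal"` or `"outlier"`.
#' @slot mechanismLog data.frame describing the perturbation applied to each
#'   planted outlier (mechanism, magnitude, number of affected features).
#' @slot seed generator seed.
#' @aliases SyntheticDataset-class
#' @exportClass SyntheticDataset
setClass("SyntheticDataset", representation(
    matrix = "IntensityMatrix",
    truth = "character",
    mechanismLog = "data.frame",
    seed = "integer"
))

setValidity("SyntheticDataset", function(object) {
    if (length(object@truth) != ncol(object@matrix))
        return("truth labels must cover every sample")
    if (sum(object@truth == "outlier") != nrow(object@mechanismLog))
        return("mechanism log must cover every planted outlier")
    TRUE
})

setMethod("show", "SyntheticDataset", function(object) {
    cat(sprintf("SyntheticDataset: %d features x %d samples, %d outliers (seed %d)\n",
                nrow(object@matrix), ncol(object@matrix),
                sum(object@truth == "outlier"), object@seed))
})

#' Generate a proteomics-like matrix with planted outliers
#'
#' Emulates label-free protein quantification on log2 scale: per-feature
#' mean abundances are normal (so the intensity marginal is log-normal),
#' features are correlated in blocks via a shared per-sample latent factor,
#' and missingness is missing-not-at-random — the probability of a dropout
#' rises as intensity falls, with the logistic intercept calibrated so the
#' realized missing fraction matches `missingFrac`.
#'
#' Outliers are planted by one of three mechanisms applied to a random
#' `affectedFrac` of features of each chosen sample: `"shift"` adds
#' `magnitude` feature-sd units, `"noise"` inflates the deviation from the
#' feature mean by factor `magnitude`, and `"shuffle"` permutes the affected
#' values within the sample.
#'
#' @param nSamples,nFeatures matrix dimensions.
#' @param outlierFrac fraction of samples planted as outliers, in \[0, 0.5);
#'   the planted count is `round(outlierFrac * nSamples)`.
#' @param mechanism `"shift"`, `"noise"` or `"shuffle"`.
#' @param magnitude mechanism strength (sd units for `"shift"`, variance
#'   scale for `"noise"`; unused for `"shuffle"`).
#' @param missingFrac overall missing fraction target, in \[0, 0.75).
#' @param seed RNG seed; fixed seed gives a bit-identical dataset.
#' @param blockSize,blockCor feature-correlation block size and intra-block
#'   correlation.
#' @param featureSd within-feature biological/technical sd (log2 units).
#' @param affectedFrac fraction of features perturbed per outlier sample.
#' @param meanLog,meanSd mean and sd of the per-feature log2 abundances.
#' @return a [SyntheticDataset-class].
#' @export
generateDataset <- function(nSamples = 60L, nFeatures = 200L,
                            outlierFrac = 0.05,
                            mechanism = c("shift", "noise", "shuffle"),
                            magnitude = 6, missingFrac = 0.2, seed = 1L,
                            blockSize = 20L, blockCor = 0.6,
                            featureSd = 0.6, affectedFrac = 0.3,
                            meanLog = 25, meanSd = 2) {
    mechanism <- match.arg(mechanism)
    if (outlierFrac < 0 || outlierFrac >= 0.5)
        stop("outlierFrac must lie in [0, 0.5)")
    if (missingFrac < 0 || missingFrac >= 0.75)
        stop("missingFrac must lie in [0, 0.75)")
    .withSeed(seed, {
        mu <- stats::rnorm(nFeatures, meanLog, meanSd)
        block <- rep(seq_len(ceiling(nFeatures / blockSize)),
                     each = blockSize)[seq_len(nFeatures)]
        z <- matrix(stats::rnorm(max(block) * nSamples), max(block))
        eps <- matrix(stats::rnorm(nFeatures * nSamples), nFeatures)
        x <- mu + featureSd * (sqrt(blockCor) * z[block, , drop = FALSE] +
                               sqrt(1 - blockCor) * eps)
        dimnames(x) <- list(sprintf("P%04d", seq_len(nFeatures)),
                            sprintf("S%03d", seq_len(nSamples)))
        nOut <- round(outlierFrac * nSamples)
        outIdx <- if (nOut > 0) sort(sample.int(nSamples, nOut)) else integer()
        nAff <- round(affectedFrac * nFeatures)
        mlog <- data.frame(sample_id = character(), mechanism = character(),
                          magnitude = numeric(), n_features = integer(),
                          stringsAsFactors = FALSE)
        for (s in outIdx) {
            aff <- sample.int(nFeatures, nAff)
            if (mechanism == "shift") {
                x[aff, s] <- x[aff, s] + magnitude * featureSd
            } else if (mechanism == "noise") {
                x[aff, s] <- mu[aff] + magnitude * (x[aff, s] - mu[aff])
            } else {
                x[aff, s] <- x[aff, s][sample.int(nAff)]
            }
            mlog <- rbind(mlog, data.frame(
                sample_id = colnames(x)[s], mechanism = mechanism,
                magnitude = magnitude, n_features = nAff,
                stringsAsFactors = FALSE))
        }
        if (missingFrac > 0) {
            scale0 <- 1
            f <- function(cc) mean(stats::plogis((cc - x) / scale0)) -
                missingFrac
            cc <- stats::uniroot(f, c(min(x) - 50, max(x) + 50))$root
            pMiss <- stats::plogis((cc - x) / scale0)
            x[matrix(stats::runif(length(x)), nrow(x)) < pMiss] <- NA_real_
        }
        truth <- rep("normal", nSamples)
        truth[outIdx] <- "outlier"
        names(truth) <- colnames(x)
        new("SyntheticDataset",
            matrix = IntensityMatrix(x, logTransformed = TRUE),
            truth = truth, mechanismLog = mlog, seed = as.integer(seed))
    })
}

#' Dataset accessors
#'
#' @param ds a [SyntheticDataset-class].
#' @name synthetic-accessors
NULL

#' @rdname synthetic-accessors
#' @export
datasetMatrix <- function(ds) ds@matrix

#' @rdname synthetic-accessors
#' @export
truthLabels <- function(ds) ds@truth

#' @rdname synthetic-accessors
#' @export
mechanismLog <- function(ds) ds@mechanismLog

#' Write a synthetic dataset as plain-text fixtures
#'
#' Writes `matrix.tsv` (log2 intensities, round-trips bit-exactly through
#' [readIntensityMatrix()]), `truth.tsv` (sample labels) and a
#' MaxQuant-dialect `proteinGroups.txt` with linear-scale `LFQ intensity`
#' columns (missing entries as zeros) that parses via [readMaxQuant()].
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFixture <- function(ds, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeIntensityMatrix(ds@matrix, file.path(dir, "matrix.tsv"))
    utils::write.table(
        data.frame(sample_id = names(ds@truth), label = ds@truth),
        file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    x <- intensities(ds@matrix)
    lin <- 2^x
    txt <- matrix(sprintf("%.17g", lin), nrow(lin))
    txt[is.na(lin)] <- "0"
    header <- c("Protein IDs",
                paste("LFQ intensity", colnames(x)),
                "Reverse", "Potential contaminant",
                "Only identified by site")
    lines <- c(paste(header, collapse = "\t"),
               paste(rownames(x),
                     apply(txt, 1L, paste, collapse = "\t"),
                     "", "", "", sep = "\t"))
    writeLines(lines, file.path(dir, "proteinGroups.txt"))
    invisible(dir)
}
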