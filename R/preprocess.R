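#' Drop features with too many missing values
#'
#' Removes features whose missing fraction across samples is strictly greater
#' than `maxMissingFrac` (default 0.75): a feature missing in exactly the
#' threshold fraction of samples is kept.  Sample set and the order of
#' surviving features are unchanged.
#'
#' @param m an [IntensityMatrix-class].
#' @param maxMissingFrac maximum tolerated missing fraction in \[0, 1\].
#' @return filtered [IntensityMatrix-class].
#' @export
filterMissingFeatures <- function(m, maxMissingFrac = 0.75) {
    stopifnot(maxMissingFrac >= 0, maxMissingFrac <= 1)
    x <- intensities(m)
    frac <- rowMeans(is.na(x))
    keep <- frac <= maxMissingFrac
    if (!any(keep))
        warning("all features removed by the missing-value filter")
    IntensityMatrix(x[keep, , drop = FALSE], isLogTransformed(m))
}

#' Impute missing values with the global observed minimum
#'
#' Every missing entry is replaced by the minimum over all observed entries
#' of the matrix, the usual proteomics stand-in for values below the
#' quantification limit.  Observed entries are untouched.
#'
#' @param m an [IntensityMatrix-class] with at least one observed value.
#' @return fully observed [IntensityMatrix-class].
#' @export
imputeMinimum <- function(m) {
    x <- intensities(m)
    if (all(is.na(x))) stop("cannot impute an all-missing matrix")
    x[is.na(x)] <- min(x, na.rm = TRUE)
    IntensityMatrix(x, isLogTransformed(m))
}

#' Normalize sample intensity distributions
#'
#' @param m a fully observed [IntensityMatrix-class] (impute first; only
#'   `method = "none"` accepts missing values).
#' @param method normalization method:
#' \describe{
#'   \item{`quantile`}{each sample's k-th order statistic is replaced by the
#'     mean k-th order statistic across samples; ties within a sample receive
#'     the mean of their tied quantile means.  The default, and the usual
#'     choice for label-free proteomics.}
#'   \item{`loess`}{per sample, a locally weighted regression (span
#'     `loessSpan`, degree 1) of the deviation from the per-feature median
#'     reference profile against the reference is fitted on log2 scale and
#'     subtracted, removing intensity-dependent bias.}
#'   \item{`standardize`}{each feature is rescaled to mean 0 / unit variance
#'     across samples; zero-variance features become all-zero with a
#'     warning.}
#'   \item{`none`}{identity.}
#' }
#' @param loessSpan loess smoothing span (default 0.7).
#' @return normalized [IntensityMatrix-class].
#' @export
normalizeIntensities <- function(m, method = c("quantile", "loess",
                                               "standardize", "none"),
                                 loessSpan = 0.7) {
    if (is.character(method) && length(method) == 1L &&
        !method %in% c("quantile", "loess", "standardize", "none"))
        stop("unknown method '", method,
             "'; valid methods: quantile, loess, standardize, none")
    method <- match.arg(method)
    if (method == "none") return(m)
    x <- intensities(m)
    if (anyNA(x))
        stop("'", method, "' normalization needs a fully observed matrix; ",
             "impute missing values first")
    out <- switch(method,
        quantile = {
            y <- limma::normalizeQuantiles(x, ties = TRUE)
            dimnames(y) <- dimnames(x)
            y
        },
        loess = .normalizeLoess(x, isLogTransformed(m), loessSpan),
        standardize = {
            sds <- apply(x, 1L, stats::sd)
            if (any(sds == 0))
                warning(sum(sds == 0),
                        " zero-variance feature(s) rescaled to all-zero")
            y <- t(scale(t(x)))
            y[sds == 0, ] <- 0
            dimnames(y) <- dimnames(x)
            y
        })
    IntensityMatrix(out, isLogTransformed(m))
}

.normalizeLoess <- function(x, logTransformed, span) {
    lx <- if (logTransformed) x else log2(pmax(x, .Machine$double.xmin))
    ref <- apply(lx, 1L, stats::median)
    for (j in seq_len(ncol(lx))) {
        dev <- lx[, j] - ref
        fit <- stats::loess(dev ~ ref, span = span, degree = 1,
                            family = "gaussian")
        lx[, j] <- lx[, j] - stats::fitted(fit)
    }
    if (logTransformed) lx else 2^lx
}

#' One-call preprocessing pipeline
#'
#' Missing-value filter, minimum imputation and normalization in the standard
#' order (filter, impute, then normalize — quantile normalization needs
#' complete columns).  Set `normalizeFirst = TRUE` to normalize the
#' already-complete case before filtering instead.
#'
#' @param m an [IntensityMatrix-class].
#' @param maxMissingFrac passed to [filterMissingFeatures()].
#' @param method,loessSpan passed to [normalizeIntensities()].
#' @param log2Transform log2-transform linear-scale input before
#'   normalization (recommended for detection; default TRUE).
#' @param normalizeFirst normalize before missing-value handling (only valid
#'   for fully observed input).
#' @return preprocessed [IntensityMatrix-class].
#' @export
preprocess <- function(m, maxMissingFrac = 0.75, method = "quantile",
                       loessSpan = 0.7, log2Transform = TRUE,
                       normalizeFirst = FALSE) {
    if (log2Transform && !isLogTransformed(m)) m <- logTransform(m)
    if (normalizeFirst)
        m <- normalizeIntensities(m, method, loessSpan)
    m <- filterMissingFeatures(m, maxMissingFrac)
    m <- imputeMinimum(m)
    if (!normalizeFirst)
        m <- normalizeIntensities(m, method, loessSpan)
    m
}
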