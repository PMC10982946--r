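#' Per-sample baseline QC statistics
#'
#' `id_count` is the number of observed (non-missing) features per sample;
#' `mean_correlation` is the mean Pearson correlation of a sample's log2
#' intensities with every other sample, computed pairwise on co-observed
#' features.  Pairs with fewer than 3 co-observed features are undefined and
#' excluded; a sample with no defined pair gets `NA` and is flagged.
#'
#' @param m an [IntensityMatrix-class] with at least 2 samples.
#' @return data.frame with columns `sample_id`, `id_count`,
#'   `mean_correlation`, `correlation_defined`.
#' @export
qcStats <- function(m) {
    x <- intensities(m)
    if (ncol(x) < 2L) stop("QC statistics need at least 2 samples")
    idCount <- colSums(!is.na(x))
    lx <- if (isLogTransformed(m)) x else log2(pmax(x, .Machine$double.xmin))
    suppressWarnings(
        C <- stats::cor(lx, use = "pairwise.complete.obs"))
    obs <- !is.na(lx)
    nPair <- crossprod(obs)                  # co-observed feature counts
    C[nPair < 3L] <- NA_real_
    diag(C) <- NA_real_
    meanCor <- rowMeans(C, na.rm = TRUE)
    defined <- rowSums(!is.na(C)) > 0L
    meanCor[!defined] <- NA_real_
    data.frame(sample_id = colnames(x), id_count = as.integer(idCount),
               mean_correlation = as.numeric(meanCor),
               correlation_defined = as.logical(defined),
               row.names = NULL)
}

#' Grubbs' test for univariate outliers
#'
#' Max-deviation outlier test: `G = max |x - mean| / sd` (or the one-sided
#' minimum/maximum variant), compared against the t-quantile critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the upper
#' `alpha/(2n)` (two-sided) or `alpha/n` (one-sided) quantile at `n - 2`
#' degrees of freedom.  In iterative mode the flagged point is removed and
#' the test repeated until no further rejection.  The reported p-value is
#' that of the max statistic.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @param mode `"two_sided"` (default), `"min"` or `"max"`.
#' @param iterative remove-and-repeat until no rejection (default TRUE).
#' @return data.frame of flagged points in removal order, with columns
#'   `index` (position in `values`), `value`, `G`, `p_value`.  Zero rows
#'   when nothing is rejected; constant input warns and flags nothing.
#' @export
grubbsTest <- function(values, alpha = 0.05,
                       mode = c("two_sided", "min", "max"),
                       iterative = TRUE) {
    mode <- match.arg(mode)
    if (length(values) < 3L) stop("Grubbs' test needs at least 3 values")
    idx <- seq_along(values)
    x <- values
    out <- data.frame(index = integer(), value = numeric(),
                      G = numeric(), p_value = numeric())
    repeat {
        n <- length(x)
        if (n < 3L) break
        s <- stats::sd(x)
        if (s == 0) {
            if (nrow(out) == 0L) warning("constant input: no outliers")
            break
        }
        dev <- switch(mode,
                      two_sided = abs(x - mean(x)),
                      min = mean(x) - x,
                      max = x - mean(x))
        hit <- which.max(dev)
        G <- dev[hit] / s
        p <- .grubbsP(G, n, mode)
        if (p >= alpha) break
        out <- rbind(out, data.frame(index = idx[hit], value = x[hit],
                                     G = G, p_value = p))
        if (!iterative) break
        x <- x[-hit]
        idx <- idx[-hit]
    }
    rownames(out) <- NULL
    out
}

.grubbsP <- function(G, n, mode) {
    sides <- if (mode == "two_sided") 2 else 1
    denom <- (n - 1)^2 - n * G^2
    if (denom <= 0) return(0)
    t <- sqrt(n * (n - 2) * G^2 / denom)
    min(1, sides * n * stats::pt(t, df = n - 2, lower.tail = FALSE))
}

.grubbsCritical <- function(n, alpha, mode = "two_sided") {
    sides <- if (mode == "two_sided") 2 else 1
    t <- stats::qt(alpha / (sides * n), df = n - 2, lower.tail = FALSE)
    ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Write per-sample QC statistics with Grubbs flags
#'
#' @param m an [IntensityMatrix-class].
#' @param path output TSV path (omit to return the table only).
#' @param alpha Grubbs significance level.
#' @return data.frame with `id_count`, `mean_correlation` and the two
#'   Grubbs flags, invisibly when written to disk.
#' @export
qcReport <- function(m, path = NULL, alpha = 0.05) {
    qc <- qcStats(m)
    qc$grubbs_flag_idcount <- FALSE
    qc$grubbs_flag_correlation <- FALSE
    g1 <- grubbsTest(qc$id_count, alpha = alpha)
    if (nrow(g1)) qc$grubbs_flag_idcount[g1$index] <- TRUE
    ok <- which(!is.na(qc$mean_correlation))
    g2 <- grubbsTest(qc$mean_correlation[ok], alpha = alpha)
    if (nrow(g2)) qc$grubbs_flag_correlation[ok[g2$index]] <- TRUE
    if (!is.null(path)) {
        utils::write.table(qc, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(qc))
    }
    qc
}
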