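#' Per-family confidence table for decision-boundary plots
#'
#' For each detector family, every configuration's mean raw scores (over the
#' rounds in which a sample was subsampled) are min-max normalized across
#' samples to \[0, 1\] and averaged over the family's configurations.
#' Constant score vectors normalize to 0.  The ensemble confidence is
#' `outlier_votes / n_models`; the final label comes from the confirmation
#' report when supplied, otherwise from the vote majority.
#'
#' @param votes a [VoteTable-class].
#' @param report optional [OutlierReport-class] supplying confirmed labels.
#' @return data.frame with one row per sample: `sample_id`, one score column
#'   per family, `confidence`, `label` (`"outlier"`/`"non-outlier"`).
#' @export
confidenceTable <- function(votes, report = NULL) {
    fams <- sub("_.*$", "", votes@configIds)
    normScores <- apply(votes@meanScores, 1L, function(s) {
        rng <- range(s, na.rm = TRUE)
        if (!is.finite(rng[1L]) || rng[1L] == rng[2L])
            return(rep(0, length(s)))
        (s - rng[1L]) / (rng[2L] - rng[1L])
    })                                       # samples x configs
    out <- data.frame(sample_id = votes@sampleIds)
    for (fam in unique(fams)) {
        cols <- which(fams == fam)
        if (!any(votes@roundsSeen[cols, , drop = FALSE] > 0)) {
            warning("family ", fam, " has no fitted configs; omitted")
            next
        }
        out[[fam]] <- rowMeans(normScores[, cols, drop = FALSE], na.rm = TRUE)
    }
    out$confidence <- votes@outlierVotes / votes@nModels
    lab <- if (is.null(report)) {
        votes@outlierVotes > votes@normalVotes
    } else {
        res <- reportTable(report)
        res$confirmed[match(votes@sampleIds, res$sample_id)]
    }
    out$label <- ifelse(lab, "outlier", "non-outlier")
    out
}

#' Joint decision-boundary plot for two detector families
#'
#' Scatters the samples in the confidence space of two families (mean
#' normalized outlier score per family).  Circles mark outliers, squares
#' non-outliers, and the background gradient interpolates the ensemble
#' confidence over a grid by inverse-distance weighting.  The plotted
#' coordinates are exported alongside the image as TSV so the rendering is
#' auditable.
#'
#' @param table a [confidenceTable()] result.
#' @param familyX,familyY family column names for the two axes.
#' @param out image path (`.png`, `.pdf`, ...); the companion TSV replaces
#'   the extension with `.tsv`.
#' @param gridN background grid resolution per axis (default 100).
#' @return `out`, invisibly.
#' @export
boundaryPlot <- function(table, familyX, familyY, out, gridN = 100L) {
    if (nrow(table) < 2L) stop("boundary plot needs at least 2 samples")
    for (fam in c(familyX, familyY))
        if (!fam %in% names(table))
            stop("family '", fam, "' not present in the confidence table")
    pts <- data.frame(x = table[[familyX]], y = table[[familyY]],
                      confidence = table$confidence, label = table$label)
    gx <- seq(0, 1, length.out = gridN)
    grid <- expand.grid(x = gx, y = gx)
    d2 <- outer(grid$x, pts$x, "-")^2 + outer(grid$y, pts$y, "-")^2
    w <- 1 / (d2 + 1e-6)
    grid$confidence <- as.vector((w %*% pts$confidence) / rowSums(w))
    p <- ggplot2::ggplot() +
        ggplot2::geom_raster(data = grid,
                             ggplot2::aes(x = .data$x, y = .data$y,
                                          fill = .data$confidence)) +
        ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c",
                                     limits = c(0, 1),
                                     name = "ensemble\nconfidence") +
        ggplot2::geom_point(data = pts,
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         shape = .data$label),
                            size = 2.5, colour = "black", fill = "white") +
        ggplot2::scale_shape_manual(
            values = c("non-outlier" = 22, "outlier" = 21), name = NULL) +
        ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1),
                                 expand = FALSE) +
        ggplot2::labs(x = paste(familyX, "confidence"),
                      y = paste(familyY, "confidence")) +
        ggplot2::theme_minimal()
    ggplot2::ggsave(out, p, width = 6, height = 5, dpi = 150)
    tsv <- sub("\\.[A-Za-z]+$", ".tsv", out)
    utils::write.table(cbind(sample_id = table$sample_id, pts), tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(out)
}
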