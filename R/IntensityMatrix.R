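#' Build an IntensityMatrix from a numeric matrix
#'
#' @param values feature-by-sample numeric matrix; `NA` entries are treated as
#'   missing.  Row and column names are required and must be unique.
#' @param logTransformed logical; are the values already on log2 scale?
#' @return an [IntensityMatrix-class] object.
#' @examples
#' x <- matrix(2^rnorm(12, 20), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
#' im <- IntensityMatrix(x)
#' im
#' @export
IntensityMatrix <- function(values, logTransformed = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(
        assays = list(intensity = values),
        metadata = list(logTransformed = isTRUE(logTransformed)))
    new("IntensityMatrix", se)
}

#' Accessors for IntensityMatrix
#'
#' `intensities()` returns the feature-by-sample matrix (with `NA` for missing
#' entries), `missingMask()` the logical missingness grid, `sampleIds()` /
#' `featureIds()` the dimension names, and `isLogTransformed()` the scale
#' flag.
#'
#' @param x an [IntensityMatrix-class].
#' @return see the individual descriptions.
#' @name intensity-accessors
NULL

#' @rdname intensity-accessors
#' @export
intensities <- function(x) assay(x, "intensity")

#' @rdname intensity-accessors
#' @export
missingMask <- function(x) is.na(assay(x, "intensity"))

#' @rdname intensity-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname intensity-accessors
#' @export
featureIds <- function(x) rownames(x)

#' @rdname intensity-accessors
#' @export
isLogTransformed <- function(x) isTRUE(metadata(x)$logTransformed)

setMethod("show", "IntensityMatrix", function(object) {
    x <- intensities(object)
    cat(sprintf("IntensityMatrix: %d features x %d samples\n",
                nrow(x), ncol(x)))
    cat(sprintf("  missing: %.1f%% | scale: %s\n",
                100 * mean(is.na(x)),
                if (isLogTransformed(object)) "log2" else "linear"))
})

#' Log2-transform an intensity matrix
#'
#' Applies `log2(x)` to the observed entries (an `offset` can guard zeros) and
#' sets the scale flag.  A matrix already flagged log2 is returned unchanged.
#'
#' @param m an [IntensityMatrix-class].
#' @param offset value added before taking logs (default 0).
#' @return log2-scale [IntensityMatrix-class].
#' @export
logTransform <- function(m, offset = 0) {
    if (isLogTransformed(m)) return(m)
    x <- intensities(m)
    if (any(x[!is.na(x)] + offset <= 0))
        stop("non-positive intensities; use a positive 'offset'")
    IntensityMatrix(log2(x + offset), logTransformed = TRUE)
}

.NA_TOKENS <- c("", "NA", "NaN")

#' Read a MaxQuant proteinGroups.txt file
#'
#' Extracts one quantification column set (`Intensity`, `iBAQ` or
#' `LFQ intensity`) from a MaxQuant proteinGroups table.  Rows flagged `+` in
#' `Reverse`, `Potential contaminant` or `Only identified by site` are
#' dropped, and zero intensities are converted to missing values (zeros in
#' MaxQuant output mean "not quantified").
#'
#' @param path path to a tab-separated proteinGroups.txt.
#' @param quantColumnPrefix one of `"Intensity"`, `"iBAQ"`,
#'   `"LFQ intensity"`; sample columns are those named
#'   `"<prefix> <sample>"`.  The bare summary column (e.g. `Intensity`
#'   with no sample suffix) is ignored.
#' @return an [IntensityMatrix-class] on linear scale.
#' @export
readMaxQuant <- function(path,
                         quantColumnPrefix = c("LFQ intensity", "Intensity",
                                               "iBAQ")) {
    quantColumnPrefix <- match.arg(quantColumnPrefix)
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- data.table::fread(path, sep = "\t", header = TRUE,
                             na.strings = .NA_TOKENS, data.table = FALSE,
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2L)
        stop("not a proteinGroups table: expected a tab-separated header row")
    pat <- paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                            quantColumnPrefix), " ")
    quantCols <- grep(pat, names(tab), value = TRUE)
    if (length(quantCols) == 0L)
        stop("no quantification columns matching prefix '",
             quantColumnPrefix, "' found")
    samples <- sub(pat, "", quantCols)
    if (anyDuplicated(samples))
        stop("duplicate sample columns for prefix '", quantColumnPrefix,
             "': ", paste(unique(samples[duplicated(samples)]),
                          collapse = ", "))
    keep <- rep(TRUE, nrow(tab))
    for (flag in c("Reverse", "Potential contaminant",
                   "Only identified by site"))
        if (flag %in% names(tab))
            keep <- keep & !(tab[[flag]] %in% "+")
    tab <- tab[keep, , drop = FALSE]
    idCol <- intersect(c("Protein IDs", "Majority protein IDs", "id"),
                       names(tab))
    ids <- if (length(idCol)) tab[[idCol[1L]]] else
        paste0("feature", seq_len(nrow(tab)))
    ids <- make.unique(ids)
    x <- vapply(quantCols, function(cn) suppressWarnings(as.numeric(tab[[cn]])),
                numeric(nrow(tab)))
    x <- matrix(x, nrow = nrow(tab),
                dimnames = list(ids, samples))
    x[!is.na(x) & x == 0] <- NA_real_
    IntensityMatrix(x, logTransformed = FALSE)
}

#' Read a generic delimited intensity matrix
#'
#' Reads a numeric table with row and column labels (tab-separated, or
#' comma-separated for `.csv` paths).  Empty cells and the tokens `NA`/`NaN`
#' mark missing values; any other non-numeric cell is a parse error reporting
#' its coordinates.
#'
#' @param path delimited file; first column holds row labels.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param logTransformed logical flag recorded on the result.
#' @return an [IntensityMatrix-class] oriented feature-by-sample.
#' @export
readIntensityMatrix <- function(path,
                                orientation = c("features_in_rows",
                                                "samples_in_rows"),
                                logTransformed = FALSE) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             row.names = NULL, check.names = FALSE,
                             colClasses = "character", quote = "\"",
                             comment.char = "")
    if (ncol(tab) < 2L) stop("matrix file needs row labels plus >= 1 column")
    rlab <- tab[[1L]]
    if (anyDuplicated(rlab))
        stop("duplicated row label: ",
             paste(unique(rlab[duplicated(rlab)]), collapse = ", "))
    clab <- names(tab)[-1L]
    if (anyDuplicated(clab))
        stop("duplicated column label: ",
             paste(unique(clab[duplicated(clab)]), collapse = ", "))
    x <- matrix(NA_real_, nrow(tab), length(clab),
                dimnames = list(rlab, clab))
    for (j in seq_along(clab)) {
        raw <- tab[[j + 1L]]
        miss <- is.na(raw) | raw %in% .NA_TOKENS
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(!miss & is.na(val))
        if (length(bad))
            stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                         raw[bad[1L]], rlab[bad[1L]], clab[j]))
        val[miss] <- NA_real_
        x[, j] <- val
    }
    if (orientation == "samples_in_rows") x <- t(x)
    IntensityMatrix(x, logTransformed = logTransformed)
}

#' Write an intensity matrix as TSV
#'
#' Features in rows, header of sample ids, full double precision (the file
#' round-trips bit-exactly through [readIntensityMatrix()]).  Missing entries
#' are written as empty cells.
#'
#' @param m an [IntensityMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntensityMatrix <- function(m, path) {
    x <- intensities(m)
    txt <- matrix(sprintf("%.17g", x), nrow(x))
    txt[is.na(x)] <- ""
    lines <- c(paste(c("feature", colnames(x)), collapse = "\t"),
               paste(rownames(x), apply(txt, 1L, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}
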