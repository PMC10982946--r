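# shared fixtures built in code

toyMatrix <- function(values, log2 = TRUE) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("P", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    IntensityMatrix(values, logTransformed = log2)
}

# tight gaussian cloud with nOut strongly shifted samples; returns a
# sample-by-feature matrix plus the outlier row indices
gaussianCloud <- function(n = 50, d = 20, nOut = 1, shiftSd = 10, sd = 0.5,
                          seed = 42) {
    set.seed(seed)
    X <- matrix(rnorm((n + nOut) * d, sd = sd), n + nOut, d)
    out <- seq(n + 1, n + nOut)
    X[out, ] <- X[out, ] + shiftSd * sd
    rownames(X) <- paste0("s", seq_len(n + nOut))
    list(X = X, outliers = out)
}

writeMaxQuantFixture <- function(path,
                                 prefix = "LFQ intensity",
                                 samples = c("A", "B")) {
    header <- c("Protein IDs", paste(prefix, samples), "Reverse",
                "Potential contaminant", "Only identified by site")
    rows <- list(
        c("P1", "100", "200", "", "", ""),
        c("P2", "0", "400", "", "", ""),     # zero -> missing
        c("P3", "500", "600", "", "", ""),
        c("REV1", "1", "2", "+", "", ""),    # reverse hit
        c("CON1", "3", "4", "", "+", ""))    # contaminant
    writeLines(c(paste(header, collapse = "\t"),
                 vapply(rows, paste, "", collapse = "\t")), path)
    path
}

# independent O(n^2) Mann-Kendall oracle: explicit pair loop and direct
# tie-group variance
mkOracle <- function(v) {
    n <- length(v)
    S <- 0
    for (i in seq_len(n - 1))
        for (j in seq(i + 1, n))
            S <- S + sign(v[j] - v[i])
    t <- as.numeric(table(v))
    t <- t[t > 1]
    varS <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
    Z <- if (S == 0 || varS <= 0) 0 else (S - sign(S)) / sqrt(varS)
    list(S = S, varS = varS, Z = Z, p = 2 * pnorm(-abs(Z)))
}
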