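# Scoring engines for the unsupervised detector pool.  All scorers take a
# sample-by-feature numeric matrix X (no missing values) and return one raw
# outlier score per sample, higher = more outlying.  Scorers that need
# randomness take an explicit seed and leave the caller's RNG untouched.

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(expr)
}

.distMatrix <- function(X, metric) {
    method <- switch(metric, euclidean = "euclidean",
                     manhattan = "manhattan", chebyshev = "maximum",
                     stop("unknown metric: ", metric))
    as.matrix(stats::dist(X, method = method))
}

# Per-metric cache of the distance matrix and row-sorted neighbour structure,
# shared by all distance-based configs fitted on the same subset.
.makeScoreCache <- function(X) {
    cache <- new.env(parent = emptyenv())
    cache$X <- X
    cache$knn <- list()
    cache$poolScores <- NULL
    cache
}

.knnInfo <- function(cache, metric) {
    info <- cache$knn[[metric]]
    if (!is.null(info)) return(info)
    D <- .distMatrix(cache$X, metric)
    n <- nrow(D)
    ord <- t(apply(D, 1L, order))          # ord[i, 1] == i (self, distance 0)
    idx <- ord[, -1L, drop = FALSE]
    d <- matrix(D[cbind(rep(seq_len(n), n - 1L), as.vector(idx))], n, n - 1L)
    info <- list(D = D, idx = idx, d = d)
    cache$knn[[metric]] <- info
    info
}

.scoreKNN <- function(info, k) info$d[, k]

.scoreAvgKNN <- function(info, k)
    rowMeans(info$d[, seq_len(k), drop = FALSE])

.scoreLOF <- function(info, k) {
    n <- nrow(info$d)
    kdist <- info$d[, k]
    N <- info$idx[, seq_len(k), drop = FALSE]
    dN <- info$d[, seq_len(k), drop = FALSE]
    reach <- pmax(matrix(kdist[N], n, k), dN)
    lrd <- 1 / rowMeans(reach)             # Inf when all reach-dists are 0
    lof <- rowMeans(matrix(lrd[N], n, k)) / lrd
    lof[!is.finite(lof)] <- 1              # duplicate points: density ratio 1
    lof
}

.scoreABOD <- function(cache, k) {
    # Fast angle-based outlier factor restricted to the k nearest neighbours:
    # low variance of the normalized angle spectrum marks an outlier, so the
    # raw score is the negated variance.
    X <- cache$X
    info <- .knnInfo(cache, "euclidean")
    n <- nrow(X)
    score <- numeric(n)
    ut <- upper.tri(matrix(0, k, k))
    for (i in seq_len(n)) {
        V <- X[info$idx[i, seq_len(k)], , drop = FALSE] -
            matrix(X[i, ], k, ncol(X), byrow = TRUE)
        G <- tcrossprod(V)
        nrm <- diag(G)
        nrm[nrm == 0] <- 1
        A <- G / outer(nrm, nrm)
        score[i] <- -stats::var(A[ut])
    }
    score[!is.finite(score)] <- 0
    score
}

.scoreECOD <- function(X) {
    # Empirical-CDF tail aggregation with a skewness-directed variant; the
    # final score is the largest of the left-, right- and skew-selected
    # aggregated negative log tail probabilities.
    n <- nrow(X)
    Ol <- Or <- Os <- numeric(n)
    for (j in seq_len(ncol(X))) {
        x <- X[, j]
        pl <- rank(x, ties.method = "max") / n
        pr <- rank(-x, ties.method = "max") / n
        m <- mean(x); s <- stats::sd(x)
        skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
        Ol <- Ol - log(pl)
        Or <- Or - log(pr)
        Os <- Os - if (skew < 0) log(pl) else log(pr)
    }
    pmax(Ol, Or, Os)
}

.scoreCBLOF <- function(X, nClusters, seed, alpha = 0.9, beta = 5) {
    n <- nrow(X)
    km <- .withSeed(seed, {
        fit <- NULL
        for (attempt in 0:4) {
            fit <- tryCatch(
                stats::kmeans(X, centers = nClusters, nstart = 1L,
                              iter.max = 100L),
                error = function(e) NULL)
            if (!is.null(fit)) break
        }
        fit
    })
    if (is.null(km)) stop("kmeans failed for CBLOF")
    sizes <- km$size
    ord <- order(sizes, decreasing = TRUE)
    csum <- cumsum(sizes[ord])
    nb <- length(sizes)
    b <- nb
    for (i in seq_len(nb - 1L)) {
        if (csum[i] >= alpha * n ||
            sizes[ord[i]] / max(sizes[ord[i + 1L]], 1) >= beta) {
            b <- i
            break
        }
    }
    large <- ord[seq_len(b)]
    centers <- km$centers
    isLarge <- km$cluster %in% large
    score <- numeric(n)
    # distance from each point to every large-cluster centre
    dl <- vapply(large, function(cl)
        sqrt(rowSums(sweep(X, 2L, centers[cl, ])^2)), numeric(n))
    dl <- matrix(dl, n)
    own <- sqrt(rowSums((X - centers[km$cluster, , drop = FALSE])^2))
    score[isLarge] <- own[isLarge]
    if (any(!isLarge))
        score[!isLarge] <- apply(dl[!isLarge, , drop = FALSE], 1L, min)
    score
}

.scoreOCSVM <- function(X, kernel, nu) {
    kern <- switch(kernel, rbf = "radial", sigmoid = "sigmoid",
                   poly = "polynomial", stop("unknown kernel: ", kernel))
    fit <- e1071::svm(x = X, type = "one-classification", kernel = kern,
                      nu = nu, scale = FALSE)
    dv <- attr(stats::predict(fit, X, decision.values = TRUE),
               "decision.values")
    -as.numeric(dv)                        # decision value: inside > 0
}

# --- isolation forest -------------------------------------------------------

.iforestHarmonic <- function(m) {
    if (m <= 1) return(0)
    2 * (log(m - 1) + 0.5772156649015329) - 2 * (m - 1) / m
}

.iforestBuild <- function(X, rows, depth, limit) {
    if (length(rows) <= 1L || depth >= limit)
        return(list(leaf = TRUE, size = length(rows)))
    sub <- X[rows, , drop = FALSE]
    rng <- apply(sub, 2L, range)
    usable <- which(rng[2L, ] > rng[1L, ])
    if (length(usable) == 0L)
        return(list(leaf = TRUE, size = length(rows)))
    q <- if (length(usable) == 1L) usable else sample(usable, 1L)
    p <- stats::runif(1L, rng[1L, q], rng[2L, q])
    left <- rows[sub[, q] < p]
    right <- rows[sub[, q] >= p]
    if (length(left) == 0L || length(right) == 0L)
        return(list(leaf = TRUE, size = length(rows)))
    list(leaf = FALSE, q = q, p = p,
         left = .iforestBuild(X, left, depth + 1L, limit),
         right = .iforestBuild(X, right, depth + 1L, limit))
}

.iforestPath <- function(node, x, depth) {
    while (!node$leaf) {
        node <- if (x[node$q] < node$p) node$left else node$right
        depth <- depth + 1L
    }
    depth + .iforestHarmonic(node$size)
}

.scoreIForest <- function(X, nTrees, seed) {
    n <- nrow(X)
    psi <- min(256L, n)
    limit <- ceiling(log2(psi))
    .withSeed(seed, {
        h <- matrix(0, n, nTrees)
        for (t in seq_len(nTrees)) {
            rows <- sample(n, psi)
            tree <- .iforestBuild(X, rows, 0L, limit)
            for (i in seq_len(n))
                h[i, t] <- .iforestPath(tree, X[i, ], 0L)
        }
        2^(-rowMeans(h) / .iforestHarmonic(psi))
    })
}

.scoreFeatureBagging <- function(X, nEstimators, seed) {
    n <- nrow(X); d <- ncol(X)
    k <- max(1L, min(10L, n - 2L))
    .withSeed(seed, {
        scores <- matrix(0, n, nEstimators)
        for (e in seq_len(nEstimators)) {
            dsub <- sample(seq.int(ceiling(d / 2), d), 1L)
            feats <- sample(d, dsub)
            cache <- .makeScoreCache(X[, feats, drop = FALSE])
            scores[, e] <- .scoreLOF(.knnInfo(cache, "euclidean"), k)
        }
        rowMeans(scores)
    })
}

.lscpPool <- function(cache) {
    # fixed candidate pool of LOF and KNN base detectors (euclidean),
    # z-normalized so scores are comparable
    if (!is.null(cache$poolScores)) return(cache$poolScores)
    n <- nrow(cache$X)
    ks <- c(5L, 10L, 15L, 20L, 25L)
    ks <- pmin(ks, max(1L, n - 2L))
    info <- .knnInfo(cache, "euclidean")
    raw <- cbind(
        vapply(ks, function(k) .scoreLOF(info, k), numeric(n)),
        vapply(ks, function(k) .scoreKNN(info, k), numeric(n)))
    colnames(raw) <- c(paste0("LOF", ks), paste0("KNN", ks))
    z <- apply(raw, 2L, function(s) {
        sdv <- stats::sd(s)
        if (sdv == 0) rep(0, length(s)) else (s - mean(s)) / sdv
    })
    cache$poolScores <- z
    z
}

.scoreLSCP <- function(cache, poolSize, seed, localRegionSize = 30L) {
    # locally selective combination: for every sample, the pool member whose
    # scores correlate best with the pseudo ground truth (pool mean) over the
    # sample's local neighbourhood supplies its score
    z <- .lscpPool(cache)
    n <- nrow(z)
    poolSize <- min(poolSize, ncol(z))
    sel <- .withSeed(seed, sample(ncol(z), poolSize))
    zp <- z[, sel, drop = FALSE]
    target <- rowMeans(zp)
    kloc <- min(localRegionSize, n - 1L)
    info <- .knnInfo(cache, "euclidean")
    out <- numeric(n)
    for (i in seq_len(n)) {
        region <- info$idx[i, seq_len(kloc)]
        tv <- target[region]
        if (stats::sd(tv) == 0) { out[i] <- target[i]; next }
        cors <- suppressWarnings(stats::cor(zp[region, , drop = FALSE], tv))
        cors[is.na(cors)] <- -Inf
        out[i] <- if (all(!is.finite(cors))) target[i]
                  else zp[i, which.max(cors)]
    }
    out
}

# --- dispatch ---------------------------------------------------------------

.neededSamples <- function(config) {
    h <- config@hyperparameters
    switch(config@family,
        LOF = , KNN = , AvgKNN = h$k + 1L,
        ABOD = h$k + 1L,
        CBLOF = h$nClusters + 1L,
        5L)
}

.scoreConfig <- function(config, X, cache = NULL) {
    if (is.null(cache)) cache <- .makeScoreCache(X)
    h <- config@hyperparameters
    switch(config@family,
        LOF = .scoreLOF(.knnInfo(cache, h$metric), h$k),
        KNN = .scoreKNN(.knnInfo(cache, h$metric), h$k),
        AvgKNN = .scoreAvgKNN(.knnInfo(cache, h$metric), h$k),
        CBLOF = .scoreCBLOF(X, h$nClusters, config@seed),
        OCSVM = .scoreOCSVM(X, h$kernel, h$nu),
        ABOD = .scoreABOD(cache, h$k),
        ECOD = .scoreECOD(X),
        IForest = .scoreIForest(X, h$nTrees, config@seed),
        FeatureBagging = .scoreFeatureBagging(X, h$nEstimators, config@seed),
        LSCP = .scoreLSCP(cache, h$poolSize, config@seed),
        stop("unknown family: ", config@family))
}

.flagScores <- function(score, contamination) {
    thr <- stats::quantile(score, 1 - contamination, names = FALSE, type = 7)
    score > thr
}
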