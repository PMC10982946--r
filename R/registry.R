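#' Create a detector configuration
#'
#' @param family detector family name (see [DetectorConfig-class]).
#' @param hyperparameters named list of family hyperparameters.
#' @param contamination assumed outlier fraction in (0, 0.5).
#' @param seed integer seed for stochastic detectors.
#' @param configId unique identifier; built from the family and
#'   hyperparameters when omitted.
#' @return a [DetectorConfig-class].
#' @export
detectorConfig <- function(family, hyperparameters = list(),
                           contamination = 0.1, seed = 1L,
                           configId = NULL) {
    if (is.null(configId)) {
        hp <- vapply(hyperparameters, function(v) paste0(v, collapse = "-"),
                     character(1))
        configId <- paste(c(family, paste0(substr(names(hp), 1, 1), hp)),
                          collapse = "_")
    }
    new("DetectorConfig", family = family,
        hyperparameters = hyperparameters,
        contamination = contamination, seed = as.integer(seed),
        configId = configId)
}

#' Registry accessors
#'
#' `configIds()` returns the ordered configuration ids, `configFamilies()`
#' the family of each configuration, `familyCounts()` a per-family tally and
#' `getConfig()` one configuration by id.
#'
#' @param registry a [ModelRegistry-class].
#' @param id a configuration id.
#' @name registry-accessors
NULL

#' @rdname registry-accessors
#' @export
configIds <- function(registry)
    vapply(registry@configs, function(cf) cf@configId, character(1))

#' @rdname registry-accessors
#' @export
configFamilies <- function(registry)
    vapply(registry@configs, function(cf) cf@family, character(1))

#' @rdname registry-accessors
#' @export
familyCounts <- function(registry)
    table(factor(configFamilies(registry), levels = .DETECTOR_FAMILIES))

#' @rdname registry-accessors
#' @export
getConfig <- function(registry, id) {
    hit <- match(id, configIds(registry))
    if (is.na(hit)) stop("unknown config id: ", id)
    registry@configs[[hit]]
}

setMethod("show", "ModelRegistry", function(object) {
    cat(sprintf("ModelRegistry '%s': %d configurations\n", object@name,
                length(object@configs)))
    fc <- familyCounts(object)
    fc <- fc[fc > 0]
    if (length(fc))
        cat("  ", paste(sprintf("%s:%d", names(fc), fc), collapse = " "),
            "\n", sep = "")
})

#' Length of a registry
#' @param x a [ModelRegistry-class].
#' @export
setMethod("length", "ModelRegistry", function(x) length(x@configs))

#' Build the full default detector pool
#'
#' Enumerates the default hyperparameter grid over the ten detector families
#' — 170 configurations in total (LOF 15, KNN 30, AvgKNN 30, CBLOF 15,
#' OCSVM 15, ABOD 15, ECOD 5, IForest 15, FeatureBagging 15, LSCP 15).  The
#' enumeration is pure and ordered: two calls produce identical id sequences,
#' and every configuration carries an explicit seed.
#'
#' @param contamination default contamination for every family except ECOD,
#'   whose grid enumerates its own contamination levels.
#' @return a [ModelRegistry-class] of 170 configurations.
#' @export
buildDefaultRegistry <- function(contamination = 0.1) {
    configs <- list()
    seed0 <- 1000L
    addCfg <- function(family, hp, cont = contamination, tag) {
        cf <- detectorConfig(family, hp, cont,
                             seed = seed0 + length(configs),
                             configId = tag)
        configs[[length(configs) + 1L]] <<- cf
    }
    for (k in c(5L, 10L, 15L, 20L, 25L)) for (mt in .KNN_METRICS)
        addCfg("LOF", list(k = k, metric = mt),
               tag = sprintf("LOF_k%d_%s", k, mt))
    knnK <- c(3L, 5L, 8L, 10L, 15L, 20L, 25L, 30L, 40L, 50L)
    for (k in knnK) for (mt in .KNN_METRICS)
        addCfg("KNN", list(k = k, metric = mt),
               tag = sprintf("KNN_k%d_%s", k, mt))
    for (k in knnK) for (mt in .KNN_METRICS)
        addCfg("AvgKNN", list(k = k, metric = mt),
               tag = sprintf("AvgKNN_k%d_%s", k, mt))
    for (nc in c(4L, 6L, 8L, 10L, 12L)) for (s in 1:3)
        addCfg("CBLOF", list(nClusters = nc, initSeed = s),
               tag = sprintf("CBLOF_c%d_s%d", nc, s))
    for (kern in .OCSVM_KERNELS)
        for (nu in c(0.05, 0.1, 0.2, 0.3, 0.4))
            addCfg("OCSVM", list(kernel = kern, nu = nu),
                   tag = sprintf("OCSVM_%s_nu%g", kern, nu))
    for (k in c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 12L, 14L, 16L, 18L, 20L,
                25L, 30L))
        addCfg("ABOD", list(k = k), tag = sprintf("ABOD_k%d", k))
    for (cont in c(0.05, 0.1, 0.15, 0.2, 0.25))
        addCfg("ECOD", list(), cont = cont,
               tag = sprintf("ECOD_cont%g", cont))
    for (nt in c(50L, 100L, 150L, 200L, 300L)) for (s in 1:3)
        addCfg("IForest", list(nTrees = nt, initSeed = s),
               tag = sprintf("IForest_t%d_s%d", nt, s))
    for (ne in c(5L, 10L, 15L)) for (s in 1:5)
        addCfg("FeatureBagging", list(nEstimators = ne, initSeed = s),
               tag = sprintf("FeatureBagging_e%d_s%d", ne, s))
    for (ps in c(4L, 6L, 8L)) for (s in 1:5)
        addCfg("LSCP", list(poolSize = ps, initSeed = s),
               tag = sprintf("LSCP_p%d_s%d", ps, s))
    # stochastic families mix the enumerated grid seed into the RNG seed so
    # replicate grid points differ
    configs <- lapply(configs, function(cf) {
        s <- cf@hyperparameters$initSeed
        if (!is.null(s)) cf@seed <- cf@seed + 104729L * as.integer(s)
        cf
    })
    new("ModelRegistry", configs = configs, name = "default")
}

#' Build a registry from a selection of configuration ids
#'
#' Subsets the default registry, preserving its order.  With no `selection`
#' argument the selection shipped with the package is used: 91 configurations
#' over seven families (LOF 15, KNN 10, AvgKNN 16, CBLOF 15, OCSVM 5,
#' FeatureBagging 15, LSCP 15), the pool retained by the simulation-driven
#' model-selection scheme (see [selectModels()]).
#'
#' @param selection character vector of config ids, or the path of a YAML
#'   selection file with a top-level `config_ids` key.  Omit for the shipped
#'   default selection.
#' @param contamination passed to [buildDefaultRegistry()].
#' @return a [ModelRegistry-class].
#' @export
buildSelectedRegistry <- function(selection = NULL, contamination = 0.1) {
    if (is.null(selection))
        selection <- system.file("extdata", "default_selection.yaml",
                                 package = "protScreen", mustWork = TRUE)
    if (length(selection) == 1L && file.exists(selection))
        selection <- unlist(yaml::read_yaml(selection)$config_ids)
    selection <- as.character(selection)
    full <- buildDefaultRegistry(contamination)
    ids <- configIds(full)
    unknown <- setdiff(selection, ids)
    if (length(unknown))
        stop("unknown config id(s): ", paste(unknown, collapse = ", "))
    if (length(selection) == 0L)
        warning("empty selection: registry has no configurations")
    keep <- ids %in% selection
    new("ModelRegistry", configs = full@configs[keep], name = "selected")
}

#' Serialize a registry or selection to YAML
#'
#' @param registry a [ModelRegistry-class].
#' @param path output file.
#' @param idsOnly write only the `config_ids` list (a selection file) rather
#'   than full configuration records.
#' @return `path`, invisibly.
#' @export
writeRegistry <- function(registry, path, idsOnly = FALSE) {
    obj <- if (idsOnly) {
        list(version = 1L, config_ids = as.list(configIds(registry)))
    } else {
        list(version = 1L, name = registry@name,
             configs = lapply(registry@configs, function(cf)
                 list(config_id = cf@configId, family = cf@family,
                      hyperparameters = cf@hyperparameters,
                      contamination = cf@contamination, seed = cf@seed)))
    }
    yaml::write_yaml(obj, path)
    invisible(path)
}

#' Fit one detector configuration and flag outliers
#'
#' Fits `config` on a complete sample-by-feature matrix and returns one raw
#' outlier score per sample (higher = more outlying) together with a flag:
#' `TRUE` when the score exceeds the configuration's contamination quantile
#' of the observed scores.  Deterministic given `config@seed`.
#'
#' @param config a [DetectorConfig-class].
#' @param data sample-by-feature numeric matrix without missing values, or an
#'   [IntensityMatrix-class] (transposed internally).
#' @return data.frame with columns `sample_id`, `raw_score`, `flag`.
#' @export
fitScore <- function(config, data) {
    if (is(data, "IntensityMatrix")) data <- t(intensities(data))
    X <- as.matrix(data)
    if (anyNA(X)) stop("fitScore needs a fully observed matrix")
    n <- nrow(X)
    if (n < 5L) stop("need at least 5 samples")
    if (n < .neededSamples(config))
        stop(.infeasible(sprintf(
            "config %s needs more than %d samples", config@configId, n)))
    if (all(apply(X, 2L, stats::sd) == 0)) {
        warning("degenerate data (zero variance everywhere): no outliers")
        return(data.frame(sample_id = .rowIds(X),
                          raw_score = rep(0, n), flag = rep(FALSE, n)))
    }
    score <- .scoreConfig(config, X)
    data.frame(sample_id = .rowIds(X), raw_score = score,
               flag = .flagScores(score, config@contamination))
}

.rowIds <- function(X)
    if (is.null(rownames(X))) paste0("sample", seq_len(nrow(X))) else
        rownames(X)

.infeasible <- function(msg)
    structure(class = c("protScreen_infeasible", "error", "condition"),
              list(message = msg, call = sys.call(-1)))
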