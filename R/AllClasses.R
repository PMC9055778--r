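#' CorrectionModel: a fitted batch-correction model
#'
#' Holds everything needed to apply a batch correction to the M-value
#' matrix it was fitted on: the batch factor, the covariate design, the
#' per-probe covariate fit, and (for the empirical-Bayes method) the raw
#' and shrunk per-batch location (gamma) and scale (delta^2) estimates with
#' their prior hyperparameters.
#'
#' @slot method one of `"eb_location_scale"`, `"mean_center"`.
#' @slot batch factor of length n samples; every sample in exactly one
#'   batch, every batch with at least two samples.
#' @slot batchVar,covariates names of the sample-sheet columns used.
#' @slot probeIds,sampleIds identifiers of the fitted matrix.
#' @slot design covariate design matrix (intercept + covariates), n x p.
#' @slot coef per-probe covariate coefficients, probes x p.
#' @slot pooledVar per-probe pooled residual variance on the M scale.
#' @slot gammaHat,deltaHat raw per-batch location/scale estimates on the
#'   standardized scale (probes x batches); empty for `mean_center`.
#' @slot gammaStar,deltaStar empirical-Bayes shrunk estimates; for
#'   `mean_center`, `gammaStar` holds the per-batch residual means on the M
#'   scale and `deltaStar` is all ones.
#' @slot priors list of hyperparameters (gamma.bar, tau2, a.prior, b.prior
#'   per batch) for the EB method.
#' @slot iterations EB iterations used per batch (integer vector).
#'
#' @seealso [fitCorrection()], [applyCorrection()]
#' @export
setClass("CorrectionModel",
    representation(
        method = "character",
        batch = "factor",
        batchVar = "character",
        covariates = "character",
        probeIds = "character",
        sampleIds = "character",
        design = "matrix",
        coef = "matrix",
        pooledVar = "numeric",
        gammaHat = "matrix",
        deltaHat = "matrix",
        gammaStar = "matrix",
        deltaStar = "matrix",
        priors = "list",
        iterations = "integer"
    )
)

setValidity("CorrectionModel", function(object) {
    msg <- character()
    if (!object@method %in% c("eb_location_scale", "mean_center"))
        msg <- c(msg, "unknown method")
    if (length(object@batch) != length(object@sampleIds))
        msg <- c(msg, "batch length must equal number of samples")
    if (any(table(object@batch) < 2))
        msg <- c(msg, "every batch must contain at least 2 samples")
    if (length(object@deltaStar) && any(object@deltaStar <= 0))
        msg <- c(msg, "shrunk scale estimates must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CorrectionModel", function(object) {
    cat("CorrectionModel (", object@method, ")\n", sep = "")
    cat("  probes:  ", length(object@probeIds), "\n", sep = "")
    cat("  samples: ", length(object@sampleIds), "\n", sep = "")
    cat("  batch:   '", object@batchVar, "' with ",
        nlevels(object@batch), " levels\n", sep = "")
    if (length(object@covariates))
        cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

#' ProbeClusters: per-probe univariate cluster models
#'
#' One cluster model per probe: the selected number of clusters k, the
#' per-sample assignments (clusters indexed 1..k in ascending centroid
#' order), centroids, sizes and BIC-by-k selection diagnostics.
#'
#' @slot probeIds,sampleIds identifiers, matching the clustered matrix.
#' @slot k integer vector of selected cluster counts (1..4).
#' @slot assignments integer matrix, probes x samples.
#' @slot centroids list of ascending numeric vectors (length k per probe).
#' @slot sizes list of integer vectors (cluster sizes, sum to n).
#' @slot bic list of named numeric vectors: the BIC of each candidate k
#'   evaluated during selection (larger is better).
#' @slot withinss numeric vector of total within-cluster sums of squares.
#'
#' @seealso [clusterProbes()], [selectOptimalK()]
#' @export
setClass("ProbeClusters",
    representation(
        probeIds = "character",
        sampleIds = "character",
        k = "integer",
        assignments = "matrix",
        centroids = "list",
        sizes = "list",
        bic = "list",
        withinss = "numeric"
    )
)

setValidity("ProbeClusters", function(object) {
    msg <- character()
    np <- length(object@probeIds)
    if (length(object@k) != np || length(object@centroids) != np)
        msg <- c(msg, "per-probe slots must have one entry per probe")
    if (nrow(object@assignments) != np ||
        ncol(object@assignments) != length(object@sampleIds))
        msg <- c(msg, "assignments must be probes x samples")
    if (any(object@k < 1L | object@k > 4L))
        msg <- c(msg, "k must lie in 1..4")
    ok <- vapply(seq_len(np), function(i) {
        ce <- object@centroids[[i]]
        length(ce) == object@k[i] && !is.unsorted(ce, strictly = TRUE)
    }, logical(1))
    if (np && !all(ok))
        msg <- c(msg, "centroids must be strictly increasing, length k")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ProbeClusters", function(object) {
    cat("ProbeClusters:", length(object@probeIds), "probes x",
        length(object@sampleIds), "samples\n")
    print(table(k = object@k))
})

#' Accessors for ProbeClusters
#'
#' @param object a [ProbeClusters-class] object.
#' @return `clusterK()`: named integer vector of selected k per probe.
#'   `clusterAssignments()`: integer matrix probes x samples.
#'   `clusterCentroids()`: named list of ascending centroid vectors.
#' @export
clusterK <- function(object) {
    stopifnot(is(object, "ProbeClusters"))
    setNames(object@k, object@probeIds)
}

#' @rdname clusterK
#' @export
clusterAssignments <- function(object) {
    stopifnot(is(object, "ProbeClusters"))
    object@assignments
}

#' @rdname clusterK
#' @export
clusterCentroids <- function(object) {
    stopifnot(is(object, "ProbeClusters"))
    setNames(object@centroids, object@probeIds)
}
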