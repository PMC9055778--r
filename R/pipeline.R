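#' PCA overview of an M-value matrix
#'
#' Probe-centred SVD of the autosomal M values (X/Y-chromosome probes are
#' removed when a `chromosome` annotation is available, since coordinated
#' X-inactivation methylation in females otherwise dominates the leading
#' components). No scaling is applied.
#'
#' @param m probes x samples M matrix.
#' @param annotation optional per-probe data.frame with a `chromosome`
#'   column (rownames or `probe_id` identify probes); absent annotation
#'   uses all probes with a warning.
#' @param n_components number of components to return (>= 4 kept where
#'   available).
#' @param center_only kept for clarity: centring is always applied,
#'   scaling never.
#' @return list with `coordinates` (samples x components),
#'   `variance_explained` (fractions, summing to <= 1), `loadings`
#'   (probes x components) and `n_probes_used`.
#' @export
pcaOverview <- function(m, annotation = NULL, n_components = 4L,
                        center_only = TRUE) {
    m <- as.matrix(m)
    if (ncol(m) < 3) stop("need at least 3 samples")
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
    ann <- normalizeAnnotation(annotation, ids)
    if (is.null(ann$chromosome)) {
        if (is.null(annotation))
            warning("no probe annotation; using all probes in the PCA")
        keep <- rep(TRUE, nrow(m))
    } else {
        keep <- !(ann$chromosome %in% c("chrX", "chrY", "X", "Y"))
    }
    mm <- m[keep, , drop = FALSE]
    mm <- mm - rowMeans(mm)
    sv <- svd(t(mm))
    nc <- min(n_components, length(sv$d))
    coords <- sv$u[, seq_len(nc), drop = FALSE] %*%
        diag(sv$d[seq_len(nc)], nc)
    dimnames(coords) <- list(colnames(m), paste0("PC", seq_len(nc)))
    list(coordinates = coords,
         variance_explained = (sv$d^2 / sum(sv$d^2))[seq_len(nc)],
         loadings = structure(sv$v[, seq_len(nc), drop = FALSE],
                              dimnames = list(rownames(mm),
                                              paste0("PC", seq_len(nc)))),
         n_probes_used = sum(keep))
}

#' Run the full probe-wise batch-correction audit
#'
#' End-to-end workflow: beta preprocessing ([shiftBetas()]), logit2
#' transform, two-stage modal clustering on the *pre-correction* data,
#' batch correction on the M scale, back-transform, per-probe diagnostics
#' (LVR, mean beta shift, maximal probe-wise beta difference,
#' classification) and factor attribution of the modal probes.
#' Deterministic given `seed`.
#'
#' @param beta probes x samples beta matrix (or `se`, below).
#' @param sheet sample sheet data.frame.
#' @param se alternatively, a `SummarizedExperiment` with a `beta` assay
#'   (e.g. from [simulateStudy()]); overrides `beta`/`sheet`.
#' @param batch_var,covariates,method,dichotomize passed to
#'   [fitCorrection()].
#' @param excluded_slides slide levels set aside in clustering stage 1.
#' @param annotation optional probe annotation (see
#'   [attributeModalProbes()]).
#' @param lvr_cut,shift_cut,alpha classification and attribution
#'   thresholds.
#' @param kmax,min_cluster_size,min_centroid_sep clustering constraints.
#' @param seed RNG seed (beta noise injection, Monte-Carlo tests).
#' @param outdir optional directory; when given, writes
#'   `reference_matrix.tsv` (4-dp rounded), `attribution.tsv` and
#'   `summary.json`.
#' @return list with `diagnostics`, `attribution`, `clusters`
#'   ([ProbeClusters-class]), `correction` ([CorrectionModel-class]),
#'   `beta_pre`, `beta_post` and `summary`.
#' @export
runPipeline <- function(beta = NULL, sheet = NULL, se = NULL,
                        batch_var = "slide",
                        covariates = c("gender", "cell_fraction"),
                        method = "eb_location_scale",
                        dichotomize = NULL,
                        excluded_slides = character(),
                        annotation = NULL,
                        lvr_cut = log2(1.5), shift_cut = 0.01,
                        alpha = 0.001,
                        kmax = 4L, min_cluster_size = 5L,
                        min_centroid_sep = 0.1,
                        seed = 1L, outdir = NULL) {
    if (!is.null(se)) {
        beta <- SummarizedExperiment::assay(se, "beta")
        sheet <- as.data.frame(SummarizedExperiment::colData(se))
        if (is.null(annotation) &&
            ncol(SummarizedExperiment::rowData(se)))
            annotation <- as.data.frame(SummarizedExperiment::rowData(se))
    }
    if (is.null(beta) || is.null(sheet))
        stop("supply either beta + sheet or se")
    covariates <- intersect(covariates, names(sheet))

    pre <- shiftBetas(as.matrix(beta), seed = seed)
    m_pre <- betaToM(pre)
    clusters <- clusterProbes(pre, sheet, excluded_slides, kmax,
                              min_cluster_size, min_centroid_sep)
    model <- fitCorrection(m_pre, sheet, batch_var, covariates, method,
                           dichotomize = dichotomize)
    post <- mToBeta(applyCorrection(m_pre, model))
    diag <- probeDiagnostics(pre, post, clusters, lvr_cut, shift_cut)
    attribution <- attributeModalProbes(clusters, sheet, annotation,
                                        alpha = alpha, seed = seed)
    summary <- c(attr(diag, "summary"),
                 list(n_probes = nrow(diag),
                      n_modal = sum(clusters@k >= 2L),
                      n_erroneously_corrected =
                          sum(diag$classification == "erroneously_corrected"),
                      n_batch_susceptible =
                          sum(diag$classification == "batch_susceptible")))
    if (!is.null(outdir)) {
        if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
        exportReferenceMatrix(diag, file.path(outdir,
                                              "reference_matrix.tsv"))
        writeSampleSheet(attribution, file.path(outdir, "attribution.tsv"))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(diagnostics = diag, attribution = attribution,
         clusters = clusters, correction = model,
         beta_pre = pre, beta_post = post, summary = summary)
}

#' Cross-dataset consensus of probe classifications
#'
#' Joins per-dataset diagnostics tables on their shared probe universe
#' (intersection of probe ids) and counts, per probe, in how many
#' datasets it was classified batch-effect susceptible or erroneously
#' corrected, with marginal tallies at the >= 1, >= 4 and all-datasets
#' thresholds.
#'
#' @param tables named list of [probeDiagnostics()] tables.
#' @return a `data.frame` with per-dataset classifications and
#'   `n_datasets_susceptible` / `n_datasets_erroneous` counts; a
#'   `"tallies"` attribute holds the marginal counts.
#' @export
consensusTable <- function(tables) {
    if (!length(tables)) stop("need at least one diagnostics table")
    if (is.null(names(tables)))
        names(tables) <- paste0("dataset", seq_along(tables))
    shared <- Reduce(intersect, lapply(tables, function(t) t$probe_id))
    if (!length(shared)) stop("no probes shared across datasets")
    cls <- vapply(tables, function(t)
        as.character(t$classification[match(shared, t$probe_id)]),
        character(length(shared)))
    cls <- matrix(cls, nrow = length(shared),
                  dimnames = list(shared, names(tables)))
    nsus <- rowSums(cls == "batch_susceptible")
    nerr <- rowSums(cls == "erroneously_corrected")
    nd <- length(tables)
    out <- data.frame(probe_id = shared, cls,
                      n_datasets_susceptible = nsus,
                      n_datasets_erroneous = nerr,
                      row.names = NULL, check.names = FALSE,
                      stringsAsFactors = FALSE)
    attr(out, "tallies") <- list(
        n_datasets = nd, n_probes = length(shared),
        susceptible_ge1 = sum(nsus >= 1),
        susceptible_ge4 = sum(nsus >= min(4, nd)),
        susceptible_all = sum(nsus == nd),
        erroneous_ge1 = sum(nerr >= 1),
        erroneous_ge4 = sum(nerr >= min(4, nd)),
        erroneous_all = sum(nerr == nd))
    out
}
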