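#' Fit a batch-correction model on an M-value matrix
#'
#' Two back-ends are available. `eb_location_scale` is a parametric
#' empirical-Bayes location/scale corrector: each probe is standardized by
#' its covariate fit and pooled residual SD, per-batch location (gamma) and
#' scale (delta^2) estimates are shrunk towards normal / inverse-gamma
#' priors whose hyperparameters are set by the method of moments across
#' probes, with posterior estimates iterated to convergence. `mean_center`
#' simply records, per probe, the per-batch means of the covariate-fit
#' residuals (no scale adjustment).
#'
#' Correction must be fitted on M values (unbounded scale); betas are not
#' guaranteed to remain in [0, 1] under location/scale adjustment.
#'
#' @param m probes x samples matrix of M values (finite, no zero-variance
#'   probes; see [shiftBetas()]).
#' @param sheet sample sheet `data.frame`, rows aligned with the matrix
#'   columns (a `sample_id` column is matched against `colnames(m)` when
#'   present).
#' @param batch_var name of the batch column (categorical).
#' @param covariates character vector of biological covariate columns to
#'   retain; categorical columns enter as factors, numeric columns
#'   linearly.
#' @param method `"eb_location_scale"` (default) or `"mean_center"`.
#' @param dichotomize optional named numeric vector: the named numeric
#'   covariates are cut into two groups at the given threshold before
#'   entering the design (e.g. `c(cell_fraction = 0.06)`).
#' @param conv,max_iter EB convergence tolerance on successive posterior
#'   estimates and iteration cap.
#' @return a [CorrectionModel-class].
#' @examples
#' se <- simulateStudy(studyConfig(probe_counts = c(clean_unimodal = 50L),
#'                                 seed = 3L))
#' m <- betaToM(shiftBetas(SummarizedExperiment::assay(se), seed = 1L))
#' fit <- fitCorrection(m, as.data.frame(SummarizedExperiment::colData(se)),
#'                      batch_var = "slide", covariates = "gender")
#' @export
fitCorrection <- function(m, sheet, batch_var, covariates = character(),
                          method = c("eb_location_scale", "mean_center"),
                          dichotomize = NULL,
                          conv = 1e-4, max_iter = 100L) {
    method <- match.arg(method)
    m <- as.matrix(m)
    if (!all(is.finite(m))) stop("M matrix must be finite")
    sheet <- alignSheet(sheet, colnames(m), ncol(m))
    if (!batch_var %in% names(sheet))
        stop("batch column '", batch_var, "' not found in sample sheet")
    missing_cov <- setdiff(covariates, names(sheet))
    if (length(missing_cov))
        stop("covariate column(s) not found: ",
             paste(missing_cov, collapse = ", "))
    batch <- droplevels(as.factor(sheet[[batch_var]]))
    if (any(table(batch) < 2))
        stop("every batch must contain at least 2 samples")

    zv <- apply(m, 1L, function(x) max(x) == min(x))
    if (any(zv))
        stop(sum(zv), " zero-variance probe(s) (e.g. '",
             rownames(m)[which(zv)[1L]], "'); run shiftBetas() with ",
             "noise injection before correcting")

    covd <- covariateDesign(sheet, covariates, dichotomize)
    if (nlevels(batch) > 1) {
        full <- cbind(covd, model.matrix(~batch)[, -1, drop = FALSE])
        if (qr(full)$rank < ncol(full))
            stop("batch confounded with covariate: the design ",
                 "(intercept + covariates + batch) is not full rank")
    }

    fit <- lmFitRows(m, covd)
    nb <- nlevels(batch)
    empty <- matrix(0, nrow(m), nb,
                    dimnames = list(rownames(m), levels(batch)))

    if (method == "mean_center") {
        gs <- empty
        for (b in levels(batch))
            gs[, b] <- rowMeans(fit$resid[, batch == b, drop = FALSE])
        if (nb == 1) gs[] <- 0  # nothing to correct
        return(new("CorrectionModel", method = method, batch = batch,
                   batchVar = batch_var, covariates = covariates,
                   probeIds = rownames(m) %||% character(),
                   sampleIds = colnames(m) %||% as.character(seq_len(ncol(m))),
                   design = covd, coef = fit$coef,
                   pooledVar = rowMeans(fit$resid^2),
                   gammaHat = empty, deltaHat = empty + 1,
                   gammaStar = gs, deltaStar = empty + 1,
                   priors = list(), iterations = integer(nb)))
    }

    ## empirical-Bayes location/scale
    batchD <- if (nb == 1) matrix(1, ncol(m), 1, dimnames = list(
        NULL, levels(batch))) else model.matrix(~0 + batch)
    X <- cbind(batchD, covd[, -1, drop = FALSE]) # batch absorbs intercept
    Bhat <- t(solve(crossprod(X), crossprod(X, t(m))))
    props <- as.numeric(table(batch)) / ncol(m)
    grand <- as.numeric(Bhat[, seq_len(nb), drop = FALSE] %*% props)
    stand_mean <- matrix(grand, nrow(m), ncol(m))
    if (ncol(covd) > 1) {
        covpart <- Bhat[, -seq_len(nb), drop = FALSE] %*%
            t(covd[, -1, drop = FALSE])
        stand_mean <- stand_mean + covpart
    }
    var_pooled <- rowMeans((m - tcrossprod(Bhat, X))^2)
    Z <- (m - stand_mean) / sqrt(var_pooled)

    gamma_hat <- empty
    delta_hat <- empty
    for (b in levels(batch)) {
        Zb <- Z[, batch == b, drop = FALSE]
        gamma_hat[, b] <- rowMeans(Zb)
        delta_hat[, b] <- apply(Zb, 1L, var)
    }
    gamma_bar <- colMeans(gamma_hat)
    tau2 <- apply(gamma_hat, 2L, var)
    a_prior <- apply(delta_hat, 2L, function(d) {
        mm <- mean(d); s2 <- var(d); (2 * s2 + mm^2) / s2
    })
    b_prior <- apply(delta_hat, 2L, function(d) {
        mm <- mean(d); s2 <- var(d); (mm * s2 + mm^3) / s2
    })

    gamma_star <- empty
    delta_star <- empty + 1
    iters <- integer(nb)
    if (nb > 1) {
        for (bi in seq_len(nb)) {
            b <- levels(batch)[bi]
            Zb <- Z[, batch == b, drop = FALSE]
            nB <- ncol(Zb)
            g_old <- gamma_hat[, b]
            d_old <- delta_hat[, b]
            it <- 0L
            repeat {
                it <- it + 1L
                g_new <- (tau2[bi] * nB * gamma_hat[, b] +
                          d_old * gamma_bar[bi]) / (tau2[bi] * nB + d_old)
                sum2 <- rowSums((Zb - g_new)^2)
                d_new <- (0.5 * sum2 + b_prior[bi]) /
                    (nB / 2 + a_prior[bi] - 1)
                change <- max(abs(g_new - g_old) / abs(g_old),
                              abs(d_new - d_old) / d_old)
                g_old <- g_new; d_old <- d_new
                if (change < conv || it >= max_iter) break
            }
            gamma_star[, b] <- g_old
            delta_star[, b] <- d_old
            iters[bi] <- it
        }
    } else {
        gamma_star[] <- 0
    }

    new("CorrectionModel", method = method, batch = batch,
        batchVar = batch_var, covariates = covariates,
        probeIds = rownames(m) %||% character(),
        sampleIds = colnames(m) %||% as.character(seq_len(ncol(m))),
        design = covd, coef = Bhat, pooledVar = var_pooled,
        gammaHat = gamma_hat, deltaHat = delta_hat,
        gammaStar = gamma_star, deltaStar = delta_star,
        priors = list(gamma_bar = gamma_bar, tau2 = tau2,
                      a_prior = a_prior, b_prior = b_prior,
                      stand_mean = stand_mean),
        iterations = iters)
}

#' Apply a fitted batch correction
#'
#' @param m the M-value matrix the model was fitted on (same samples, same
#'   order).
#' @param model a [CorrectionModel-class] from [fitCorrection()].
#' @return the corrected M matrix, same shape. A single-batch model
#'   returns the input unchanged.
#' @export
applyCorrection <- function(m, model) {
    stopifnot(is(model, "CorrectionModel"))
    m <- as.matrix(m)
    if (ncol(m) != length(model@sampleIds))
        stop("sample count does not match the fitted model")
    if (!is.null(colnames(m)) && length(model@sampleIds) &&
        !identical(colnames(m), model@sampleIds))
        stop("sample ids do not match the fitted model")
    batch <- model@batch
    if (nlevels(batch) == 1) return(m)
    bi <- as.integer(batch)
    if (model@method == "mean_center")
        return(m - model@gammaStar[, bi, drop = FALSE])
    Z <- (m - model@priors$stand_mean) / sqrt(model@pooledVar)
    Z <- (Z - model@gammaStar[, bi, drop = FALSE]) /
        sqrt(model@deltaStar[, bi, drop = FALSE])
    Z * sqrt(model@pooledVar) + model@priors$stand_mean
}

#' One-step batch correction of a beta matrix
#'
#' Convenience wrapper: shift betas, transform to M, fit and apply the
#' correction for each batch variable in turn, and transform back to beta.
#'
#' @inheritParams fitCorrection
#' @param beta probes x samples beta matrix.
#' @param batch_var one or more batch columns, corrected sequentially in
#'   the order given.
#' @param seed seed for the [shiftBetas()] noise injection.
#' @param ... passed on to [fitCorrection()].
#' @return corrected beta matrix (strictly inside (0, 1)).
#' @export
correctBatch <- function(beta, sheet, batch_var, covariates = character(),
                         method = "eb_location_scale", seed = 1L, ...) {
    m <- betaToM(shiftBetas(beta, seed = seed))
    for (bv in batch_var) {
        fit <- fitCorrection(m, sheet, bv, covariates, method, ...)
        m <- applyCorrection(m, fit)
    }
    mToBeta(m)
}

## helpers ------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

alignSheet <- function(sheet, ids, n) {
    sheet <- as.data.frame(sheet)
    if (!is.null(ids) && "sample_id" %in% names(sheet)) {
        idx <- match(ids, as.character(sheet$sample_id))
        if (anyNA(idx))
            stop("sample sheet is missing entries for some matrix columns")
        sheet <- sheet[idx, , drop = FALSE]
    }
    if (nrow(sheet) != n)
        stop("sample sheet rows must match matrix columns")
    sheet
}

covariateDesign <- function(sheet, covariates, dichotomize = NULL) {
    if (!length(covariates))
        return(matrix(1, nrow(sheet), 1,
                      dimnames = list(NULL, "(Intercept)")))
    d <- sheet[covariates]
    for (v in names(dichotomize)) {
        if (!v %in% covariates) next
        d[[v]] <- factor(ifelse(d[[v]] > dichotomize[[v]], "high", "low"),
                         levels = c("low", "high"))
    }
    for (v in covariates)
        if (is.character(d[[v]]) || is.logical(d[[v]]))
            d[[v]] <- factor(d[[v]])
    model.matrix(~., data = d)
}

# per-probe least-squares fit of rows of y on design x
lmFitRows <- function(y, x) {
    coef <- t(solve(crossprod(x), crossprod(x, t(y))))
    list(coef = coef, resid = y - tcrossprod(coef, x))
}
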