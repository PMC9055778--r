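#' Exact optimal univariate k-means
#'
#' Globally optimal partition of a numeric vector into `k` clusters
#' minimising the within-cluster sum of squares, computed by dynamic
#' programming over the sorted data (clusters of the optimum are
#' contiguous intervals of the sorted values). Deterministic; no
#' initialisation sensitivity.
#'
#' @param x numeric vector of finite values, `length(x) >= k`.
#' @param k number of clusters, `>= 1`.
#' @return list with `assignments` (cluster index per input element, 1..k
#'   in ascending centroid order), `centroids` (ascending), `sizes` and
#'   `withinss` (total within-cluster sum of squares).
#' @examples
#' ckmeans1d(c(1, 2, 4, 5), 2) # {1,2} {4,5}, withinss 1
#' @export
ckmeans1d <- function(x, k) {
    if (!is.numeric(x) || any(!is.finite(x)))
        stop("x must be finite numeric")
    if (k > length(x)) stop("k must not exceed length(x)")
    .ckmeans_dp(as.numeric(x), as.integer(k))
}

#' BIC of a univariate cluster model
#'
#' Scores a fitted clustering as a Gaussian mixture: cluster-wise means,
#' cluster-wise (ML) variances and mixing proportions, 3k - 1 free
#' parameters. Returned in the larger-is-better orientation
#' `2 logL - (3k - 1) log n`. Cluster variances are floored at `var_floor`
#' so that degenerate tight clusters (singletons, ties) remain scorable.
#'
#' @param x the clustered data.
#' @param assignments integer cluster index per element.
#' @param var_floor minimum cluster variance (beta^2 units).
#' @return the BIC (numeric scalar; larger is better).
#' @export
clusteringBIC <- function(x, assignments, var_floor = 1e-6) {
    n <- length(x)
    stopifnot(length(assignments) == n, n >= 1)
    ks <- sort(unique(assignments))
    k <- length(ks)
    ll <- 0
    for (c in ks) {
        xi <- x[assignments == c]
        nc <- length(xi)
        mu <- mean(xi)
        v <- max(sum((xi - mu)^2) / nc, var_floor)
        ll <- ll + sum(dnorm(xi, mu, sqrt(v), log = TRUE)) +
            nc * log(nc / n)
    }
    2 * ll - (3 * k - 1) * log(n)
}

#' Select the optimal number of clusters for one probe
#'
#' Fits `k = 1..kmax` by [ckmeans1d()], ranks the candidates by
#' [clusteringBIC()] and takes the two best. A candidate `k` qualifies iff
#' every cluster holds at least `min_cluster_size` samples and adjacent
#' centroids are separated by at least `min_centroid_sep` (a beta
#' difference of 0.1, i.e. 10% methylation, by default); `k = 1` always
#' qualifies. The largest qualifying k of the top two is retained, and any
#' k above 4 is recoded to 4.
#'
#' Ties in BIC are broken towards smaller k.
#'
#' @param x numeric vector of beta values for one probe.
#' @param kmax largest k considered (capped at 4 internally).
#' @param min_cluster_size minimum samples per cluster for k >= 2.
#' @param min_centroid_sep minimum adjacent-centroid beta difference.
#' @param var_floor passed to [clusteringBIC()].
#' @return list with `k`, `assignments`, `centroids`, `sizes`,
#'   `withinss`, `bic` (named vector over candidate k).
#' @export
selectOptimalK <- function(x, kmax = 4L, min_cluster_size = 5L,
                           min_centroid_sep = 0.1, var_floor = 1e-6) {
    n <- length(x)
    if (n <= min_cluster_size)
        stop("need more than min_cluster_size samples")
    kcand <- seq_len(min(kmax, n))
    fits <- lapply(kcand, function(k) ckmeans1d(x, k))
    bic <- vapply(seq_along(kcand), function(i)
        clusteringBIC(x, fits[[i]]$assignments, var_floor), numeric(1))
    names(bic) <- kcand
    # two best by BIC; ties towards smaller k (order() is stable)
    top2 <- kcand[order(-bic)][seq_len(min(2L, length(kcand)))]
    qualifies <- function(k) {
        if (k == 1L) return(TRUE)
        f <- fits[[k]]
        all(f$sizes >= min_cluster_size) &&
            all(diff(f$centroids) >= min_centroid_sep)
    }
    ok <- Filter(qualifies, top2)
    k <- if (length(ok)) max(ok) else 1L
    k <- min(k, 4L)
    f <- fits[[k]]
    list(k = as.integer(k), assignments = f$assignments,
         centroids = f$centroids, sizes = as.integer(f$sizes),
         withinss = f$withinss, bic = bic)
}

#' Two-stage modal clustering of every probe
#'
#' Stage 1 selects the optimal k per probe on the samples *retained* after
#' setting aside slides with the strongest batch-effects (so technical
#' structure does not inflate k); stage 2 re-clusters **all** samples at
#' that fixed k. With an empty exclusion list this reduces to single-stage
#' selection.
#'
#' @param beta probes x samples beta matrix.
#' @param sheet sample sheet with a `slide` column (only needed when
#'   `excluded_slides` is non-empty).
#' @param excluded_slides character vector of slide levels set aside
#'   during stage 1 (typically chosen from PCA review).
#' @inheritParams selectOptimalK
#' @return a [ProbeClusters-class] with all samples assigned.
#' @export
clusterProbes <- function(beta, sheet = NULL, excluded_slides = character(),
                          kmax = 4L, min_cluster_size = 5L,
                          min_centroid_sep = 0.1, var_floor = 1e-6) {
    beta <- as.matrix(beta)
    keep <- rep(TRUE, ncol(beta))
    if (length(excluded_slides)) {
        if (is.null(sheet) || !"slide" %in% names(as.data.frame(sheet)))
            stop("excluding slides requires a sample sheet with a ",
                 "'slide' column")
        sheet <- alignSheet(sheet, colnames(beta), ncol(beta))
        keep <- !(as.character(sheet$slide) %in% as.character(excluded_slides))
        if (!any(keep)) stop("excluded_slides removes every sample")
        if (sum(keep) < 2L * min_cluster_size)
            stop("excluded_slides leaves too few samples for clustering")
    }
    np <- nrow(beta)
    kvec <- integer(np)
    assign <- matrix(NA_integer_, np, ncol(beta),
                     dimnames = dimnames(beta))
    cents <- vector("list", np)
    sizes <- vector("list", np)
    bics <- vector("list", np)
    wss <- numeric(np)
    for (i in seq_len(np)) {
        sel <- selectOptimalK(beta[i, keep], kmax, min_cluster_size,
                              min_centroid_sep, var_floor)
        if (all(keep)) {
            fit <- sel
        } else {
            # stage 2: all samples, k fixed from stage 1
            f <- ckmeans1d(beta[i, ], sel$k)
            fit <- list(k = sel$k, assignments = f$assignments,
                        centroids = f$centroids,
                        sizes = as.integer(f$sizes),
                        withinss = f$withinss, bic = sel$bic)
        }
        kvec[i] <- fit$k
        assign[i, ] <- fit$assignments
        cents[[i]] <- fit$centroids
        sizes[[i]] <- fit$sizes
        bics[[i]] <- fit$bic
        wss[i] <- fit$withinss
    }
    new("ProbeClusters",
        probeIds = rownames(beta) %||% as.character(seq_len(np)),
        sampleIds = colnames(beta) %||% as.character(seq_len(ncol(beta))),
        k = kvec, assignments = assign, centroids = cents,
        sizes = sizes, bic = bics, withinss = wss)
}
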