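#' Cluster-aware sample variance
#'
#' Within-cluster sums of squares pooled across clusters and divided by
#' `n - 1`. With a single cluster this is the textbook sample variance;
#' with k > 1 it measures dispersion around cluster means, so a corrector
#' that destroys genuine clustering *inflates* it even while shrinking the
#' ordinary variance.
#'
#' @param x numeric vector (beta values for one probe).
#' @param assignments cluster index per element (any labelling).
#' @return the pooled variance (beta^2 units).
#' @examples
#' clusterAwareVariance(c(0.2, 0.4, 0.6), rep(1, 3)) # ordinary var: 0.04
#' @export
clusterAwareVariance <- function(x, assignments) {
    n <- length(x)
    if (n < 2) stop("need at least 2 samples")
    if (length(assignments) != n || anyNA(assignments))
        stop("every sample must carry a cluster assignment")
    ss <- 0
    for (c in unique(assignments)) {
        xi <- x[assignments == c]
        ss <- ss + sum((xi - mean(xi))^2)
    }
    ss / (n - 1)
}

#' Log-variance ratio (LVR)
#'
#' `log2` of the ratio of cluster-aware sample variance after versus
#' before correction, with the cluster assignments fixed from the
#' *pre-correction* clustering. LVR > 0 means correction inflated the
#' (cluster-aware) variance — the signature of erroneously corrected
#' clustering; LVR < 0 means variance was removed as intended.
#'
#' A probe with zero pre-correction variance has no defined ratio and
#' returns `NA` (it is reported, never dropped).
#'
#' @param pre,post beta values for one probe before/after correction,
#'   same sample order.
#' @param assignments pre-correction cluster indices.
#' @return the LVR (numeric scalar, possibly `NA`).
#' @examples
#' x <- c(0.1, 0.2, 0.8, 0.9)
#' lvr(x, x, rep(1, 4)) # 0
#' @export
lvr <- function(pre, post, assignments) {
    if (length(pre) != length(post)) stop("pre/post length mismatch")
    v_pre <- clusterAwareVariance(pre, assignments)
    v_post <- clusterAwareVariance(post, assignments)
    if (v_pre == 0) return(NA_real_)
    log2(v_post / v_pre)
}

#' Mean beta shift induced by correction
#'
#' Mean over samples of `|post - pre|`. The absolute convention is the
#' default: a signed mean would cancel opposing batch moves and defeat the
#' 0.01 classification gate.
#'
#' @inheritParams lvr
#' @param signed if `TRUE`, return the signed mean difference instead.
#' @return non-negative scalar (signed convention may be negative).
#' @export
meanBetaShift <- function(pre, post, signed = FALSE) {
    if (length(pre) != length(post)) stop("pre/post length mismatch")
    d <- post - pre
    if (signed) mean(d) else mean(abs(d))
}

#' Maximal probe-wise beta difference
#'
#' The span of per-sample beta changes induced by correction:
#' `|max(d) - min(d)|` with `d = post - pre`. A uniform shift scores 0;
#' large values flag probes where one or more batches were moved much
#' further than others.
#'
#' @inheritParams lvr
#' @return non-negative scalar.
#' @export
maxProbewiseBetaDiff <- function(pre, post) {
    if (length(pre) != length(post)) stop("pre/post length mismatch")
    d <- post - pre
    abs(max(d) - min(d))
}

#' Adjustment group of a beta-difference statistic
#'
#' Bins the maximal probe-wise beta difference into the low (< 0.01),
#' moderate ([0.01, 0.10]) and high (> 0.10) adjustment groups.
#'
#' @param stat non-negative statistic (vectorised).
#' @return factor with levels low/moderate/high.
#' @export
adjustmentGroup <- function(stat) {
    if (any(stat < 0, na.rm = TRUE)) stop("statistic must be >= 0")
    cut(stat, breaks = c(-Inf, 0.01, 0.10, Inf), right = FALSE,
        labels = c("low", "moderate", "high")) ->
        g
    # cut() with right = FALSE puts 0.10 in "high"; the moderate interval
    # is closed on both ends, so pull the boundary back
    g[!is.na(stat) & stat == 0.10] <- "moderate"
    g
}

#' Classify a probe from its LVR and mean beta shift
#'
#' `lvr >= lvr_cut` with `shift >= shift_cut` flags erroneous correction;
#' `lvr <= -lvr_cut` with the same shift gate flags batch-effect
#' susceptibility; anything else (including missing LVR) is unclassified.
#' Default cut-offs: a 50% variance change (`log2(1.5) = 0.584`) and a
#' mean beta shift of 0.01.
#'
#' @param lvr,shift numeric vectors (recycled to common length).
#' @param lvr_cut,shift_cut classification cut-offs.
#' @return factor with levels `erroneously_corrected`,
#'   `batch_susceptible`, `unclassified`.
#' @export
classifyProbes <- function(lvr, shift, lvr_cut = log2(1.5),
                           shift_cut = 0.01) {
    out <- rep("unclassified", max(length(lvr), length(shift)))
    lvr <- rep_len(lvr, length(out))
    shift <- rep_len(shift, length(out))
    ok <- !is.na(lvr) & !is.na(shift)
    out[ok & lvr >= lvr_cut & shift >= shift_cut] <- "erroneously_corrected"
    out[ok & lvr <= -lvr_cut & shift >= shift_cut] <- "batch_susceptible"
    factor(out, levels = c("erroneously_corrected", "batch_susceptible",
                           "unclassified"))
}

#' Per-probe correction diagnostics table
#'
#' Computes, for every probe, the cluster-aware variances before and after
#' correction (assignments fixed from the pre-correction clustering), the
#' LVR, mean beta shift, maximal probe-wise beta difference, ordinary SDs,
#' adjustment group and classification. Probes without a cluster model are
#' scored with k = 1.
#'
#' @param pre,post beta matrices before/after correction (same dimnames).
#' @param clusters a [ProbeClusters-class] computed on `pre`, or `NULL`
#'   for all-unimodal scoring.
#' @param lvr_cut,shift_cut classification cut-offs, see
#'   [classifyProbes()].
#' @return a `data.frame` with one row per probe and a
#'   `"summary"` attribute holding the mean/median maximal probe-wise beta
#'   difference and the percentage of probes per adjustment group.
#' @export
probeDiagnostics <- function(pre, post, clusters = NULL,
                             lvr_cut = log2(1.5), shift_cut = 0.01) {
    pre <- as.matrix(pre); post <- as.matrix(post)
    if (!identical(dim(pre), dim(post)))
        stop("pre and post matrices must have identical dimensions")
    np <- nrow(pre)
    ids <- rownames(pre) %||% as.character(seq_len(np))
    kvec <- rep(1L, np)
    amat <- NULL
    if (!is.null(clusters)) {
        stopifnot(is(clusters, "ProbeClusters"))
        if (!is.null(colnames(pre)) &&
            !identical(colnames(pre), clusters@sampleIds))
            stop("cluster model samples do not match the beta matrices")
        idx <- match(ids, clusters@probeIds)
        amat <- clusters@assignments
        kvec <- ifelse(is.na(idx), 1L, clusters@k[idx])
        kidx <- idx
    }
    one <- rep(1L, ncol(pre))
    res <- vapply(seq_len(np), function(i) {
        a <- if (!is.null(amat) && !is.na(kidx[i])) amat[kidx[i], ] else one
        c(var_pre = clusterAwareVariance(pre[i, ], a),
          var_post = clusterAwareVariance(post[i, ], a),
          mean_beta_shift = meanBetaShift(pre[i, ], post[i, ]),
          max_probewise_beta_diff = maxProbewiseBetaDiff(pre[i, ], post[i, ]))
    }, numeric(4))
    res <- t(res)
    lvr_v <- ifelse(res[, "var_pre"] == 0, NA_real_,
                    log2(res[, "var_post"] / res[, "var_pre"]))
    grp <- adjustmentGroup(res[, "max_probewise_beta_diff"])
    out <- data.frame(
        probe_id = ids,
        k = kvec,
        var_pre = res[, "var_pre"], var_post = res[, "var_post"],
        lvr = lvr_v,
        mean_beta_shift = res[, "mean_beta_shift"],
        max_probewise_beta_diff = res[, "max_probewise_beta_diff"],
        sd_pre = apply(pre, 1L, sd), sd_post = apply(post, 1L, sd),
        adjustment_group = grp,
        classification = classifyProbes(lvr_v, res[, "mean_beta_shift"],
                                        lvr_cut, shift_cut),
        row.names = NULL, stringsAsFactors = FALSE)
    pct <- 100 * as.numeric(table(grp)) / np
    attr(out, "summary") <- list(
        mean_max_probewise_beta_diff = mean(res[, "max_probewise_beta_diff"]),
        median_max_probewise_beta_diff =
            median(res[, "max_probewise_beta_diff"]),
        pct_low = pct[1L], pct_moderate = pct[2L], pct_high = pct[3L])
    out
}

#' Export a reference matrix of probe diagnostics
#'
#' Writes the diagnostics table as TSV with numeric columns rounded to 4
#' decimal places.
#'
#' @param diag a table from [probeDiagnostics()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
exportReferenceMatrix <- function(diag, path) {
    cols <- c("probe_id", "lvr", "mean_beta_shift",
              "max_probewise_beta_diff", "sd_pre", "sd_post", "k",
              "adjustment_group", "classification")
    out <- diag[cols]
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "k"
    out[num] <- lapply(out[num], round, digits = 4L)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
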