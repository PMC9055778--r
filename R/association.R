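#' Association between cluster membership and a categorical factor
#'
#' Two-sided Fisher exact test on the cluster x factor contingency table.
#' For tables too large for exact computation (more than `max_cells`
#' cells) the caller should use [chisqMonteCarlo()] instead; this function
#' then refuses rather than silently approximating.
#'
#' @param assignments cluster index per sample.
#' @param factor_ categorical factor per sample.
#' @param max_cells largest table size handled exactly.
#' @return the p value.
#' @export
fisherClusterAssociation <- function(assignments, factor_, max_cells = 30L) {
    tab <- table(assignments, factor_)
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("need at least 2 clusters and 2 factor levels")
    if (length(tab) > max_cells)
        stop("contingency table has ", length(tab), " cells (> ",
             max_cells, "); use chisqMonteCarlo()")
    fisher.test(tab, workspace = 2e7)$p.value
}

#' Monte-Carlo chi-square association test
#'
#' Chi-square test of independence with a simulated null: `B` tables are
#' drawn with fixed margins and `p = (1 + #{chi2* >= chi2}) / (B + 1)`.
#' Deterministic given `seed`. Used where the contingency table is too
#' large for the Fisher exact network algorithm.
#'
#' @inheritParams fisherClusterAssociation
#' @param B number of simulated tables (>= 999).
#' @param seed RNG seed.
#' @return the simulated p value.
#' @export
chisqMonteCarlo <- function(assignments, factor_, B = 10000L, seed = 1L) {
    if (B < 999L) stop("B must be >= 999")
    tab <- table(assignments, factor_)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
        warning("degenerate contingency table; returning p = 1")
        return(1)
    }
    set.seed(seed)
    suppressWarnings(
        chisq.test(tab, simulate.p.value = TRUE, B = B))$p.value
}

#' Association between cluster membership and a continuous covariate
#'
#' One-way ANOVA F test of `covariate ~ cluster` — e.g. the estimated
#' immune-cell fraction against methylation clusters.
#'
#' @param assignments cluster index per sample.
#' @param covariate numeric vector, finite.
#' @return the F-test p value (1 when the covariate is constant).
#' @export
continuousAssociation <- function(assignments, covariate) {
    if (length(unique(assignments)) < 2)
        stop("need at least 2 clusters")
    if (any(!is.finite(covariate))) stop("covariate must be finite")
    if (all(table(assignments) < 2))
        stop("no cluster contributes within-cluster variance")
    if (max(covariate) == min(covariate)) return(1)
    fit <- lm(covariate ~ factor(assignments))
    av <- anova(fit)
    p <- av[["Pr(>F)"]][1L]
    if (is.na(p)) 1 else p
}

#' Hardy-Weinberg exact test on genotype-like cluster sizes
#'
#' Levene-Haldane exact test: conditional on the allele counts, the
#' probabilities of every possible heterozygote count are enumerated and
#' those no larger than the observed configuration's are summed. Cluster
#' sizes in ascending-centroid order are mapped to genotype counts
#' (AA, AB, BB); for two clusters the two groups map to the two most
#' populous genotype classes — larger cluster to the common homozygote,
#' smaller to the heterozygote — and the absent minor-homozygote class is
#' set to 0.
#'
#' @param counts 2 or 3 non-negative cluster sizes in ascending centroid
#'   order (or genotype counts directly when length 3).
#' @return the exact p value; 1 for a monomorphic configuration.
#' @examples
#' hweExact(c(25, 50, 25)) # the most probable configuration
#' @export
hweExact <- function(counts) {
    if (!length(counts) %in% 2:3 || any(counts < 0))
        stop("counts must be 2 or 3 non-negative cluster sizes")
    if (sum(counts) < 1) stop("total count must be >= 1")
    if (length(counts) == 2L) {
        counts <- sort(counts, decreasing = TRUE)
        counts <- c(counts, 0)
    }
    nAA <- counts[1L]; nAB <- counts[2L]; nBB <- counts[3L]
    n <- nAA + nAB + nBB
    nA <- 2L * nAA + nAB
    nB <- 2L * nBB + nAB
    if (nA == 0 || nB == 0) return(1)
    # heterozygote counts share the parity of nA
    hs <- seq(nA %% 2L, min(nA, nB), by = 2L)
    # log P(h | n, nA) up to the common constant
    logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
        lfactorial((nB - hs) / 2) + hs * log(2)
    logp <- logp - max(logp)
    p <- exp(logp) / sum(exp(logp))
    obs <- p[hs == nAB]
    sum(p[p <= obs * (1 + 1e-12)])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p values (monotone in rank, capped at 1),
#' computed within a factor across probes.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed).
#' @return adjusted p values.
#' @export
bhFdr <- function(p_values) {
    if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
        stop("p values must lie in [0, 1]")
    p.adjust(p_values, method = "BH")
}

#' Attribute modal probes to biological and technical factors
#'
#' For every modal probe (k >= 2), tests the association of the cluster
#' assignments with gender, batch (slide), superbatch (Fisher exact,
#' switching to the Monte-Carlo chi-square for large tables) and cell
#' composition (one-way ANOVA), plus the Hardy-Weinberg exact test on the
#' cluster sizes of autosomal probes with 2 or 3 clusters. p values are
#' BH-adjusted within each factor across probes; a factor is attributed at
#' adjusted p < `alpha`. HWE consistency means *non*-rejection. Probes
#' with no attribution are labelled unknown.
#'
#' @param clusters a [ProbeClusters-class].
#' @param sheet sample sheet with `gender`, `slide`, `superbatch`,
#'   `cell_fraction` columns (missing columns skip that factor with a
#'   warning).
#' @param annotation optional per-probe data.frame with logical columns
#'   such as `snp_at_site`, `snp_within_10bp`, `cross_hybridising` and a
#'   `chromosome` column (chrX/chrY probes are excluded from the HWE
#'   test); rownames or a `probe_id` column identify probes.
#' @param alpha FDR-adjusted significance cut-off (default 0.001).
#' @param mc_B,seed Monte-Carlo chi-square parameters.
#' @return a `data.frame` with one row per modal probe: per-factor
#'   adjusted p values and significance flags, `hwe_consistent`,
#'   annotation flags and an `unknown` flag; an `"intersections"`
#'   attribute tallies the attribution combinations (upset-style).
#' @export
attributeModalProbes <- function(clusters, sheet, annotation = NULL,
                                 alpha = 0.001, mc_B = 10000L, seed = 1L) {
    stopifnot(is(clusters, "ProbeClusters"))
    sheet <- alignSheet(sheet, clusters@sampleIds,
                        length(clusters@sampleIds))
    modal <- which(clusters@k >= 2L)
    ids <- clusters@probeIds[modal]
    out <- data.frame(probe_id = ids, k = clusters@k[modal],
                      stringsAsFactors = FALSE)
    if (!length(modal)) {
        attr(out, "intersections") <- table(character())
        return(out)
    }

    factors <- list(gender = "gender", batch = "slide",
                    superbatch = "superbatch")
    testCat <- function(a, f) {
        tab <- table(a, f)
        if (min(dim(tab)) < 2) return(NA_real_)
        if (length(tab) > 30L)
            chisqMonteCarlo(a, f, B = mc_B, seed = seed)
        else fisherClusterAssociation(a, f)
    }
    for (fac in names(factors)) {
        col <- factors[[fac]]
        if (!col %in% names(sheet)) {
            warning("column '", col, "' missing; skipping ", fac)
            next
        }
        p <- vapply(modal, function(i)
            testCat(clusters@assignments[i, ], sheet[[col]]), numeric(1))
        out[[paste0("p_", fac)]] <- bhFdr(p)
        out[[paste0("sig_", fac)]] <-
            !is.na(out[[paste0("p_", fac)]]) &
            out[[paste0("p_", fac)]] < alpha
    }
    if ("cell_fraction" %in% names(sheet)) {
        p <- vapply(modal, function(i)
            continuousAssociation(clusters@assignments[i, ],
                                  sheet$cell_fraction), numeric(1))
        out$p_cell <- bhFdr(p)
        out$sig_cell <- !is.na(out$p_cell) & out$p_cell < alpha
    } else warning("column 'cell_fraction' missing; skipping cell factor")

    ## HWE on autosomal probes with 2 or 3 clusters
    ann <- normalizeAnnotation(annotation, ids)
    autosomal <- if (!is.null(ann$chromosome))
        !(ann$chromosome %in% c("chrX", "chrY", "X", "Y"))
    else rep(TRUE, length(ids))
    kk <- clusters@k[modal]
    p_hwe <- rep(NA_real_, length(ids))
    testable <- autosomal & kk %in% 2:3
    p_hwe[testable] <- vapply(which(testable), function(j)
        hweExact(clusters@sizes[[modal[j]]]), numeric(1))
    out$p_hwe <- bhFdr(p_hwe)
    out$hwe_consistent <- !is.na(out$p_hwe) & out$p_hwe >= alpha

    for (fl in c("snp_at_site", "snp_within_10bp", "cross_hybridising"))
        if (!is.null(ann[[fl]])) out[[fl]] <- as.logical(ann[[fl]])

    sig_cols <- grep("^sig_", names(out), value = TRUE)
    flag_cols <- c(sig_cols, "hwe_consistent",
                   intersect(c("snp_at_site", "snp_within_10bp",
                               "cross_hybridising"), names(out)))
    any_attr <- Reduce(`|`, lapply(flag_cols, function(cn)
        !is.na(out[[cn]]) & out[[cn]]), rep(FALSE, nrow(out)))
    out$unknown <- !any_attr

    combo <- apply(out[flag_cols], 1L, function(r)
        paste(flag_cols[!is.na(r) & as.logical(r)], collapse = "+"))
    combo[combo == ""] <- "unknown"
    attr(out, "intersections") <- sort(table(combo), decreasing = TRUE)
    out
}

normalizeAnnotation <- function(annotation, ids) {
    if (is.null(annotation)) return(list())
    ann <- as.data.frame(annotation)
    key <- if ("probe_id" %in% names(ann)) ann$probe_id else rownames(ann)
    ann <- ann[match(ids, key), , drop = FALSE]
    as.list(ann)
}
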