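# Independent oracles used to validate the package's core computations.
# These are deliberately naive (enumeration / closed forms) and share no
# code with the implementation paths they check.

# Brute-force optimal contiguous partition of sorted data into k clusters:
# enumerate every set of k-1 cut points and minimise total within-SS.
bruteForceCkmeans <- function(x, k) {
    xs <- sort(x)
    n <- length(xs)
    ss <- function(v) sum((v - mean(v))^2)
    if (k == 1) return(list(withinss = ss(xs), centroids = mean(xs)))
    cuts <- utils::combn(n - 1, k - 1)
    best <- Inf
    best_cent <- NULL
    for (j in seq_len(ncol(cuts))) {
        bounds <- c(0, cuts[, j], n)
        tot <- 0
        cent <- numeric(k)
        for (c in seq_len(k)) {
            seg <- xs[(bounds[c] + 1):bounds[c + 1]]
            tot <- tot + ss(seg)
            cent[c] <- mean(seg)
        }
        if (tot < best) { best <- tot; best_cent <- cent }
    }
    list(withinss = best, centroids = best_cent)
}

# Hardy-Weinberg exact test by full enumeration: conditional on the allele
# counts, weight every genotype configuration by its multinomial
# coefficient times 2^het and sum the normalised weights no larger than
# the observed one.
enumHweP <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    nA <- 2 * nAA + nAB
    nB <- 2 * nBB + nAB
    if (nA == 0 || nB == 0) return(1)
    hs <- seq(0, min(nA, nB))
    hs <- hs[(nA - hs) %% 2 == 0]
    w <- vapply(hs, function(h) {
        aa <- (nA - h) / 2
        bb <- (nB - h) / 2
        exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2))
    }, numeric(1))
    w <- w / sum(w)
    obs <- w[hs == nAB]
    sum(w[w <= obs * (1 + 1e-12)])
}

# Fisher 2x2 two-sided p by hypergeometric closed form: sum the
# probabilities of all tables (same margins) no more probable than the
# observed one.
hyper2x2P <- function(tab) {
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0, k - n2); hi <- min(k, m)
    d <- dhyper(lo:hi, m, n2, k)
    sum(d[d <= dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# small default study used by several files (cached per test run)
defaultStudy <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateStudy(studyConfig())
        cache
    }
})
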