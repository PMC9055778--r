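test_that("clusterAwareVariance pools within-cluster sums of squares", {
    expect_equal(clusterAwareVariance(c(0.2, 0.4, 0.6), rep(1, 3)), 0.04)
    expect_equal(clusterAwareVariance(c(0, 0, 1, 1), c(1, 1, 2, 2)), 0)
    expect_equal(clusterAwareVariance(c(0, 0.2, 1, 1.2), c(1, 1, 2, 2)),
                 0.04 / 3)
    expect_error(clusterAwareVariance(0.5, 1), "at least 2")
    expect_error(clusterAwareVariance(c(0.5, 0.6), c(1, NA)), "assignment")
})

test_that("one-cluster pooling reduces to the textbook sample variance", {
    set.seed(12)
    for (i in 1:25) {
        x <- runif(sample(5:50, 1))
        expect_equal(clusterAwareVariance(x, rep(1, length(x))), var(x),
                     tolerance = 1e-12)
    }
})

test_that("optimal partitions never inflate the pooled variance", {
    set.seed(13)
    for (i in 1:25) {
        x <- runif(30)
        k <- sample(2:4, 1)
        a <- ckmeans1d(x, k)$assignments
        expect_lte(clusterAwareVariance(x, a), var(x) + 1e-12)
    }
})

test_that("lvr has the documented orientation and cut-off values", {
    x <- c(0.1, 0.15, 0.5, 0.55, 0.9, 0.95)
    a <- rep(1:3, each = 2)
    expect_equal(lvr(x, x, a), 0)
    # a 50% variance increase sits exactly at the classification cut-off
    y <- mean(x) + (x - mean(x)) * sqrt(1.5)
    expect_lt(abs(lvr(x, y, rep(1, 6)) - 0.584), 1e-3)
    y <- mean(x) + (x - mean(x)) / sqrt(1.5)
    expect_lt(abs(lvr(x, y, rep(1, 6)) - (-0.584)), 1e-3)
    # antisymmetry
    set.seed(3)
    p <- runif(20); q <- runif(20); a2 <- rep(1:2, 10)
    expect_equal(lvr(p, q, a2), -lvr(q, p, a2))
    # zero pre-variance: flagged missing, never an error
    expect_true(is.na(lvr(rep(0.5, 10), runif(10), rep(1, 10))))
})

test_that("meanBetaShift uses the absolute convention by default", {
    x <- rep(0.4, 4)
    expect_equal(meanBetaShift(x, x), 0)
    expect_equal(meanBetaShift(x, x + 0.02), 0.02)
    d <- c(0.02, -0.02, 0.02, -0.02)
    expect_equal(meanBetaShift(x, x + d), 0.02)
    expect_equal(meanBetaShift(x, x + d, signed = TRUE), 0)
    expect_error(meanBetaShift(x, x[1:2]), "mismatch")
})

test_that("maxProbewiseBetaDiff is the span of per-sample changes", {
    x <- c(0.1, 0.2, 0.3)
    expect_equal(maxProbewiseBetaDiff(x, x + 0.05), 0)
    expect_equal(maxProbewiseBetaDiff(c(0.5, 0.5), c(0.45, 0.55)), 0.10)
    expect_equal(maxProbewiseBetaDiff(x, c(0.1, 0.25, 0.28)), 0.07)
})

test_that("adjustment groups use the closed moderate interval", {
    g <- adjustmentGroup(c(0.005, 0.01, 0.05, 0.10, 0.2, 0))
    expect_equal(as.character(g),
                 c("low", "moderate", "moderate", "moderate", "high",
                   "low"))
    expect_error(adjustmentGroup(-0.1), ">= 0")
})

test_that("classification applies the LVR and shift gates jointly", {
    expect_equal(as.character(classifyProbes(1, 0.05)),
                 "erroneously_corrected")
    expect_equal(as.character(classifyProbes(-1, 0.05)),
                 "batch_susceptible")
    expect_equal(as.character(classifyProbes(-1, 0.005)), "unclassified")
    expect_equal(as.character(classifyProbes(NA, 0.05)), "unclassified")
    # non-strict at the cut-offs
    expect_equal(as.character(classifyProbes(log2(1.5), 0.01)),
                 "erroneously_corrected")
    # monotone: growing |lvr| or shift never de-classifies
    set.seed(5)
    for (i in 1:50) {
        l <- rnorm(1); s <- runif(1, 0, 0.1)
        c0 <- as.character(classifyProbes(l, s))
        c1 <- as.character(classifyProbes(l * 1.5, s + 0.01))
        if (c0 != "unclassified") expect_equal(c1, c0)
    }
})

test_that("probeDiagnostics of an identity correction is all-null", {
    set.seed(19)
    b <- matrix(runif(200, 0.05, 0.95), 20,
                dimnames = list(sprintf("p%02d", 1:20),
                                sprintf("s%02d", 1:10)))
    d <- probeDiagnostics(b, b)
    expect_true(all(d$lvr == 0))
    expect_true(all(d$adjustment_group == "low"))
    expect_true(all(d$classification == "unclassified"))
    s <- attr(d, "summary")
    expect_equal(s$pct_low + s$pct_moderate + s$pct_high, 100)
    # probes without a cluster model fall back to k = 1
    expect_true(all(d$k == 1L))
})

test_that("the reference-matrix export rounds to 4 decimals", {
    b <- matrix(runif(40, 0.2, 0.8), 4,
                dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
    d <- probeDiagnostics(b, b + 0.0123456)
    path <- withr::local_tempfile(fileext = ".tsv")
    exportReferenceMatrix(d, path)
    back <- read.delim(path)
    expect_equal(back$mean_beta_shift, round(d$mean_beta_shift, 4))
    expect_named(back, c("probe_id", "lvr", "mean_beta_shift",
                         "max_probewise_beta_diff", "sd_pre", "sd_post",
                         "k", "adjustment_group", "classification"))
})
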