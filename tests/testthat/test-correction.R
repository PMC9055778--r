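makeM <- function(nprobe, n, sd = 0.3, seed = 1) {
    set.seed(seed)
    matrix(rnorm(nprobe * n, 0, sd), nprobe, n,
           dimnames = list(sprintf("p%03d", seq_len(nprobe)),
                           sprintf("s%03d", seq_len(n))))
}

test_that("single-batch correction is the identity", {
    m <- makeM(50, 20)
    sheet <- data.frame(sample_id = colnames(m), slide = "one")
    for (method in c("eb_location_scale", "mean_center")) {
        fit <- fitCorrection(m, sheet, "slide", method = method)
        expect_equal(applyCorrection(m, fit), m, tolerance = 1e-10)
    }
})

test_that("a pure additive batch shift is estimated and removed", {
    m <- makeM(400, 40, sd = 0.2, seed = 4)
    d <- 1.3
    batch <- rep(c("a", "b"), each = 20)
    m[, batch == "b"] <- m[, batch == "b"] + d
    sheet <- data.frame(sample_id = colnames(m), slide = batch)
    fit <- fitCorrection(m, sheet, "slide")
    # location estimates differ by d on the M scale (gamma is standardized
    # by the pooled SD, so rescale before comparing)
    est_d <- mean((fit@gammaStar[, "b"] - fit@gammaStar[, "a"]) *
                  sqrt(fit@pooledVar))
    se3 <- 3 * 0.2 * sqrt(2 / 20) / sqrt(400)
    expect_lt(abs(est_d - d), max(se3, 0.02))
    corrected <- applyCorrection(m, fit)
    gap <- rowMeans(corrected[, batch == "b"]) -
        rowMeans(corrected[, batch == "a"])
    expect_lt(mean(abs(gap)), 0.05)
})

test_that("a declared covariate effect survives correction", {
    set.seed(8)
    n <- 60
    gender <- rep(c("F", "M"), 30)
    batch <- rep(c("a", "b", "c"), each = 20)
    delta <- 2
    m <- makeM(300, n, sd = 0.3, seed = 15)
    m <- m + outer(rep(1, 300), (gender == "M") * delta)
    m <- m + outer(rep(1, 300), c(a = -0.5, b = 0.2, c = 0.6)[batch])
    sheet <- data.frame(sample_id = colnames(m), slide = batch,
                        gender = gender)
    fit <- fitCorrection(m, sheet, "slide", covariates = "gender")
    corrected <- applyCorrection(m, fit)
    eff <- rowMeans(corrected[, gender == "M"]) -
        rowMeans(corrected[, gender == "F"])
    expect_lt(abs(mean(eff) - delta) / delta, 0.05)
})

test_that("mean_center removes per-batch residual means exactly", {
    m <- makeM(100, 30, seed = 6)
    batch <- rep(c("a", "b", "c"), 10)
    m[, batch == "c"] <- m[, batch == "c"] + 0.8
    sheet <- data.frame(sample_id = colnames(m), slide = batch)
    fit <- fitCorrection(m, sheet, "slide", method = "mean_center")
    corrected <- applyCorrection(m, fit)
    for (b in unique(batch)) {
        bm <- rowMeans(corrected[, batch == b])
        expect_equal(bm, rowMeans(corrected[, batch == "a"]),
                     tolerance = 1e-8)
    }
    # idempotence: correcting the corrected data changes nothing
    fit2 <- fitCorrection(corrected, sheet, "slide",
                          method = "mean_center")
    expect_equal(applyCorrection(corrected, fit2), corrected,
                 tolerance = 1e-10)
})

test_that("EB shrinkage moves betas less than mean centering on null data", {
    m <- makeM(2000, 24, sd = 0.4, seed = 10)
    batch <- rep(c("a", "b", "c", "d"), each = 6)
    sheet <- data.frame(sample_id = colnames(m), slide = batch)
    pre <- mToBeta(m)
    shift_of <- function(method) {
        fit <- fitCorrection(m, sheet, "slide", method = method)
        post <- mToBeta(applyCorrection(m, fit))
        mean(abs(post - pre))
    }
    expect_lt(shift_of("eb_location_scale"), shift_of("mean_center"))
})

test_that("degenerate designs are rejected with clear diagnostics", {
    m <- makeM(20, 12)
    sheet <- data.frame(sample_id = colnames(m),
                        slide = rep(c("a", "b"), each = 6),
                        gender = rep(c("F", "M"), each = 6))
    expect_error(fitCorrection(m, sheet, "slide", covariates = "gender"),
                 "confounded")
    m2 <- m
    m2[3, ] <- 0.7
    sheet2 <- data.frame(sample_id = colnames(m), slide = rep(c("a", "b"), 6))
    expect_error(fitCorrection(m2, sheet2, "slide"), "shiftBetas")
    fit <- fitCorrection(m, sheet2, "slide")
    expect_error(applyCorrection(m[, 1:6], fit), "sample")
    expect_error(fitCorrection(m, sheet2, "array"), "batch column")
})

test_that("the EB corrector agrees with the reference implementation", {
    skip_if_not_installed("sva")
    m <- makeM(500, 36, sd = 0.5, seed = 33)
    batch <- rep(c("a", "b", "c"), each = 12)
    m <- m + outer(rnorm(500, 0, 0.4), c(a = -1, b = 0, c = 1)[batch])
    gender <- rep_len(c("F", "M"), 36)
    m <- m + outer(rep(0.5, 500), (gender == "M") * 1)
    sheet <- data.frame(sample_id = colnames(m), slide = batch,
                        gender = gender)
    fit <- fitCorrection(m, sheet, "slide", covariates = "gender")
    ours <- applyCorrection(m, fit)
    mod <- stats::model.matrix(~gender)
    ref <- suppressMessages(
        sva::ComBat(m, batch = batch, mod = mod, par.prior = TRUE))
    expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("correctBatch round-trips through the M scale", {
    se <- defaultStudy()
    b <- SummarizedExperiment::assay(se, "beta")[1:100, ]
    sheet <- as.data.frame(SummarizedExperiment::colData(se))
    out <- correctBatch(b, sheet, "slide", covariates = "gender")
    expect_equal(dim(out), dim(b))
    expect_true(all(out > 0 & out < 1))
})
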