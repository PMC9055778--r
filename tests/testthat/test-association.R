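test_that("Fisher exact association matches the hypergeometric form", {
    a <- rep(1:2, each = 10)
    f <- rep(c("x", "y"), each = 10)
    expect_equal(fisherClusterAssociation(a, f), 2 / choose(20, 10),
                 tolerance = 1e-10)
    expect_equal(fisherClusterAssociation(rep(1:2, each = 10),
                                          rep(c("x", "y"), 10)), 1)
    set.seed(23)
    for (i in 1:100) {
        tab <- matrix(rpois(4, 8) + 1, 2)
        a <- rep(1:2, rowSums(tab))
        f <- unlist(lapply(1:2, function(r)
            rep(c("x", "y"), tab[r, ])))
        expect_equal(fisherClusterAssociation(a, f), hyper2x2P(tab),
                     tolerance = 1e-7)
    }
    expect_error(fisherClusterAssociation(rep(1, 10), rep("x", 10)),
                 "at least 2")
    big <- expand.grid(a = 1:4, f = letters[1:10])
    expect_error(fisherClusterAssociation(big$a, big$f), "chisqMonteCarlo")
})

test_that("Monte-Carlo chi-square is seeded and calibrated", {
    # strong dependence: p at the simulation floor
    a <- rep(1:4, each = 24)
    f <- rep(letters[1:6], c(24, 24, 24, 8, 8, 8))
    p <- chisqMonteCarlo(a, f, B = 1999L, seed = 2L)
    expect_lte(p, 1 / 2000 + 1e-12)
    expect_identical(p, chisqMonteCarlo(a, f, B = 1999L, seed = 2L))
    # independent factor: large p in most runs
    set.seed(17)
    ps <- vapply(1:50, function(s)
        chisqMonteCarlo(sample(rep(1:3, 32)), rep(letters[1:8], 12),
                        B = 999L, seed = s), numeric(1))
    expect_gte(mean(ps > 0.05), 0.9)
    expect_warning(p1 <- chisqMonteCarlo(rep(1, 10), rep("x", 10)),
                   "degenerate")
    expect_equal(p1, 1)
    expect_error(chisqMonteCarlo(1:4, c(1, 1, 2, 2), B = 10L), "999")
})

test_that("continuous association is an ANOVA F test", {
    a <- rep(1:2, each = 48)
    expect_equal(continuousAssociation(a, rep(0.5, 96)), 1)
    set.seed(3)
    cf <- c(rnorm(48, 0.03, 0.02), rnorm(48, 0.30, 0.02))
    expect_lt(continuousAssociation(a, cf), 1e-10)
    expect_error(continuousAssociation(rep(1, 10), runif(10)),
                 "at least 2")
    expect_error(continuousAssociation(a, c(NA, runif(95))), "finite")
    # relabelling clusters never changes the p value
    p1 <- continuousAssociation(a, cf)
    expect_equal(continuousAssociation(3 - a, cf), p1)
})

test_that("the HWE exact test agrees with full enumeration", {
    expect_gt(hweExact(c(25, 50, 25)), 0.9)
    expect_lt(hweExact(c(50, 0, 50)), 1e-20)
    # every genotype table with up to 50 samples
    for (n in c(5, 17, 33, 50)) {
        for (nAA in 0:n) {
            for (nAB in 0:(n - nAA)) {
                nBB <- n - nAA - nAB
                expect_equal(hweExact(c(nAA, nAB, nBB)),
                             enumHweP(nAA, nAB, nBB),
                             tolerance = 1e-10)
            }
        }
    }
    # monomorphic configurations are vacuously consistent
    expect_equal(hweExact(c(50, 0, 0)), 1)
})

test_that("two-cluster sizes map to the rare-allele genotype pattern", {
    # 81/18 behaves like hom-major/het with no minor homozygote: in HWE
    expect_gte(hweExact(c(18, 81)), 0.001)
    expect_equal(hweExact(c(18, 81)), hweExact(c(81, 18)))
    expect_equal(hweExact(c(81, 18)), enumHweP(81, 18, 0))
    # a 50/50 split cannot be hom/het under HWE
    expect_lt(hweExact(c(50, 50)), 0.001)
    expect_error(hweExact(c(5, 5, 5, 5)), "2 or 3")
})

test_that("BH adjustment is the standard step-up procedure", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
    set.seed(29)
    for (i in 1:20) {
        p <- runif(50)
        adj <- bhFdr(p)
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
        # monotone in rank
        o <- order(p)
        expect_true(all(diff(adj[o]) >= -1e-15))
    }
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("attribution flags the generating factor of modal probes", {
    se <- defaultStudy()
    truth <- as.data.frame(SummarizedExperiment::rowData(se))
    keep <- truth$archetype %in% c("gender_bimodal", "cell_gradient",
                                   "asm_trimodal")
    b <- shiftBetas(SummarizedExperiment::assay(se, "beta")[keep, ],
                    seed = 1L)
    sheet <- as.data.frame(SummarizedExperiment::colData(se))
    cl <- clusterProbes(b)
    att <- attributeModalProbes(cl, sheet, annotation = NULL, seed = 1L)
    tt <- truth[keep, ][match(att$probe_id, truth$probe_id[keep]), ]
    gi <- tt$archetype == "gender_bimodal"
    ci <- tt$archetype == "cell_gradient"
    ai <- tt$archetype == "asm_trimodal"
    expect_gt(mean(att$sig_gender[gi]), 0.9)
    expect_gt(mean(att$sig_cell[ci]), 0.8)
    expect_gt(mean(att$hwe_consistent[ai]), 0.9)
    # gender probes are not HWE-attributed wholesale, nor cell probes to
    # gender: the factors separate
    expect_lt(mean(att$sig_gender[ci]), 0.2)
    expect_true(!is.null(attr(att, "intersections")))
})

test_that("attribution handles empty and partial inputs gracefully", {
    b <- matrix(runif(60, 0.4, 0.6), 6,
                dimnames = list(paste0("p", 1:6), paste0("s", 1:10)))
    cl <- clusterProbes(b)  # all unimodal
    sheet <- data.frame(sample_id = colnames(b),
                        gender = rep(c("F", "M"), 5),
                        slide = rep(c("a", "b"), each = 5),
                        superbatch = "x",
                        cell_fraction = runif(10))
    att <- attributeModalProbes(cl, sheet)
    expect_equal(nrow(att), 0)
    # a missing covariate column only skips that factor
    set.seed(2)
    b2 <- rbind(p1 = c(runif(5, 0.05, 0.1), runif(5, 0.85, 0.9)))
    colnames(b2) <- paste0("s", 1:10)
    cl2 <- clusterProbes(b2)
    expect_warning(
        att2 <- attributeModalProbes(cl2, sheet[setdiff(names(sheet),
                                                        "cell_fraction")]),
        "cell_fraction")
    expect_false("sig_cell" %in% names(att2))
})
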