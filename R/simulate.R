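#' Configuration for a synthetic Infinium-like study
#'
#' Builds the parameter list consumed by [simulateStudy()]. The defaults
#' describe a desk-scale study: 8 slides of 12 arrays (96 samples, a
#' 450K-like 6 x 2 slide layout) in 2 superbatches, and 2,000 probes split
#' across six archetypes. Effects are additive on the M scale; betas are
#' produced by the inverse logit2 transform.
#'
#' Archetypes: `clean_unimodal` (noise only), `batch_susceptible`
#' (independent per-slide shifts of SD `batch_sd_m`), `asm_trimodal`
#' (a C-to-T SNP at the probed CpG: Hardy-Weinberg genotypes at minor
#' allele frequency `maf` mapped to the three `asm` beta centroids),
#' `gender_bimodal` (males at the higher `gender` centroid),
#' `cell_gradient` (M proportional to the sample immune-cell fraction,
#' which is drawn from a low/high mixture), and `boundary_constant`
#' (a constant near-boundary beta, exercising the zero-variance path of
#' [shiftBetas()]).
#'
#' @param n_slides,arrays_per_slide slide layout; `slide_rows * slide_cols`
#'   must equal `arrays_per_slide`.
#' @param n_superbatches number of processing runs; slides are split into
#'   contiguous superbatches.
#' @param slide_rows,slide_cols array positions on a slide.
#' @param probe_counts named integer vector over the six archetypes.
#' @param maf minor allele frequency for ASM probes, in (0, 0.5].
#' @param batch_sd_m SD of the per-slide additive M shift for susceptible
#'   probes.
#' @param position_slope_m additive M trend per slide row (centred).
#' @param noise_sd_m per-observation Gaussian noise SD on the M scale.
#' @param centroids_beta list with elements `asm` (3 ascending betas),
#'   `gender` (female, male) and `cell` (low, high immune fraction).
#' @param balanced if `TRUE`, genotypes and gender are spread uniformly
#'   over slides; if `FALSE` (default) ASM minor-allele carriers are
#'   concentrated into the leading slides and gender is mildly skewed by
#'   slide half, the configuration under which undeclared clustering is
#'   erroneously corrected.
#' @param seed integer RNG seed.
#' @return a `StudyConfig` list.
#' @export
studyConfig <- function(n_slides = 8L, arrays_per_slide = 12L,
                        n_superbatches = 2L,
                        slide_rows = 6L, slide_cols = 2L,
                        probe_counts = c(clean_unimodal = 1400L,
                                         batch_susceptible = 200L,
                                         asm_trimodal = 150L,
                                         gender_bimodal = 100L,
                                         cell_gradient = 100L,
                                         boundary_constant = 50L),
                        maf = 0.3,
                        batch_sd_m = 0.5,
                        position_slope_m = 0.02,
                        noise_sd_m = 0.15,
                        centroids_beta = list(asm = c(0.1, 0.5, 0.9),
                                              gender = c(0.3, 0.7),
                                              cell = c(0.2, 0.6)),
                        balanced = FALSE,
                        seed = 1L) {
    archetypes <- c("clean_unimodal", "batch_susceptible", "asm_trimodal",
                    "gender_bimodal", "cell_gradient", "boundary_constant")
    pc <- rep(0L, length(archetypes))
    names(pc) <- archetypes
    pc[names(probe_counts)] <- as.integer(probe_counts)
    if (any(pc < 0)) stop("probe counts must be >= 0")
    if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
    if (slide_rows * slide_cols != arrays_per_slide)
        stop("slide_rows * slide_cols must equal arrays_per_slide")
    if (n_superbatches < 1L || n_superbatches > n_slides)
        stop("n_superbatches must lie in 1..n_slides")
    structure(list(
        n_slides = as.integer(n_slides),
        arrays_per_slide = as.integer(arrays_per_slide),
        n_superbatches = as.integer(n_superbatches),
        slide_rows = as.integer(slide_rows),
        slide_cols = as.integer(slide_cols),
        probe_counts = pc, maf = maf, batch_sd_m = batch_sd_m,
        position_slope_m = position_slope_m, noise_sd_m = noise_sd_m,
        centroids_beta = centroids_beta, balanced = isTRUE(balanced),
        seed = as.integer(seed)), class = "StudyConfig")
}

#' Simulate an Infinium-like methylation study with ground truth
#'
#' Generates a beta matrix, sample sheet and per-probe truth table under
#' the archetype model described in [studyConfig()]. Deterministic given
#' the config seed.
#'
#' @param config a [studyConfig()] list.
#' @return a `SummarizedExperiment` with assay `beta`, the sample sheet as
#'   `colData`, the truth table (`archetype`, `true_k`) as `rowData`, and
#'   `metadata()` entries `config`, `genotypes` (ASM probes x samples,
#'   minor-allele counts) and `slideShifts` (susceptible probes x slides,
#'   true M shifts).
#' @examples
#' se <- simulateStudy(studyConfig(probe_counts = c(clean_unimodal = 10L),
#'                                 seed = 7L))
#' dim(se)
#' @export
simulateStudy <- function(config = studyConfig()) {
    stopifnot(inherits(config, "StudyConfig"))
    set.seed(config$seed)
    n <- config$n_slides * config$arrays_per_slide

    ## ---- sample sheet ----
    slide <- rep(seq_len(config$n_slides), each = config$arrays_per_slide)
    pos_row <- rep(rep(seq_len(config$slide_rows),
                       each = config$slide_cols), config$n_slides)
    pos_col <- rep(seq_len(config$slide_cols),
                   config$slide_rows * config$n_slides)
    sb_of_slide <- cut(seq_len(config$n_slides), config$n_superbatches,
                       labels = FALSE)
    superbatch <- paste0("SB", sb_of_slide[slide])
    gender <- character(n)
    for (s in seq_len(config$n_slides)) {
        idx <- which(slide == s)
        m <- length(idx)
        if (config$balanced) {
            g <- rep(c("M", "F"), length.out = m)
        } else {
            # mild skew by slide half; never a constant within slide
            pM <- if (s <= config$n_slides / 2) 0.7 else 0.3
            nM <- max(1L, min(m - 1L, rbinom(1L, m, pM)))
            g <- c(rep("M", nM), rep("F", m - nM))
        }
        gender[idx] <- sample(g)
    }
    treatment <- sample(rep(c("ctrl", "trt"), length.out = n))
    hi <- runif(n) < 0.2
    cell_fraction <- ifelse(hi,
        pmin(pmax(rnorm(n, 0.30, 0.02), 0.20), 0.40),
        pmin(pmax(rnorm(n, 0.03, 0.01), 0.001), 0.12))
    sheet <- data.frame(
        sample_id = sprintf("S%02dR%02dC%02d", slide, pos_row, pos_col),
        slide = factor(paste0("slide", sprintf("%02d", slide))),
        position_row = pos_row, position_col = pos_col,
        superbatch = factor(superbatch), gender = factor(gender),
        treatment = factor(treatment), cell_fraction = cell_fraction,
        stringsAsFactors = FALSE)

    ## ---- probes ----
    pc <- config$probe_counts
    total <- sum(pc)
    archetype <- rep(names(pc), pc)
    probe_id <- sprintf("cg%06d", seq_len(total))
    true_k <- c(clean_unimodal = 1L, batch_susceptible = 1L,
                asm_trimodal = 3L, gender_bimodal = 2L,
                cell_gradient = 2L, boundary_constant = 1L)[archetype]

    M <- matrix(0, nrow = total, ncol = n,
                dimnames = list(probe_id, sheet$sample_id))
    cen <- config$centroids_beta
    l2 <- function(b) log2(b / (1 - b))

    is_clean <- archetype == "clean_unimodal"
    is_bs <- archetype == "batch_susceptible"
    is_asm <- archetype == "asm_trimodal"
    is_gen <- archetype == "gender_bimodal"
    is_cell <- archetype == "cell_gradient"
    is_bnd <- archetype == "boundary_constant"

    # unimodal base levels for clean and susceptible probes
    base <- l2(runif(sum(is_clean | is_bs), 0.15, 0.85))
    M[is_clean | is_bs, ] <- base

    # per-slide additive shifts for susceptible probes
    shifts <- matrix(rnorm(sum(is_bs) * config$n_slides,
                           sd = config$batch_sd_m),
                     nrow = sum(is_bs), ncol = config$n_slides,
                     dimnames = list(probe_id[is_bs], levels(sheet$slide)))
    M[is_bs, ] <- M[is_bs, ] + shifts[, slide, drop = FALSE]

    # ASM: HWE genotypes; minor-allele count 0/1/2 maps to the descending
    # asm centroids (the T allele reads as unmethylated)
    q <- config$maf
    genotypes <- matrix(0L, nrow = sum(is_asm), ncol = n,
                        dimnames = list(probe_id[is_asm], sheet$sample_id))
    if (sum(is_asm)) {
        asm_levels <- l2(rev(cen$asm)) # genotype 0,1,2 -> high,mid,low M
        for (i in seq_len(sum(is_asm))) {
            g <- rbinom(n, 2L, q)
            if (config$balanced) {
                g <- sample(g)
            } else {
                # concentrate minor-allele carriers into the leading slides
                g <- sort(g, decreasing = TRUE)
            }
            genotypes[i, ] <- g
        }
        M[is_asm, ] <- matrix(asm_levels[genotypes + 1L],
                              nrow = sum(is_asm))
    }

    # gender bimodality: males at the higher centroid
    g_lev <- l2(cen$gender)
    M[is_gen, ] <- rep(ifelse(sheet$gender == "M", g_lev[2], g_lev[1]),
                       each = sum(is_gen))

    # immune-cell gradient, linear in the cell fraction on the M scale
    c_lev <- l2(cen$cell)
    cf_scale <- (cell_fraction - 0.03) / (0.30 - 0.03)
    M[is_cell, ] <- rep(c_lev[1] + (c_lev[2] - c_lev[1]) * cf_scale,
                        each = sum(is_cell))

    # slide-position trend (centred over rows) and observation noise,
    # applied to every non-constant archetype
    live <- !is_bnd
    trend <- config$position_slope_m * (pos_row - (config$slide_rows + 1) / 2)
    M[live, ] <- M[live, ] + rep(trend, each = sum(live)) +
        matrix(rnorm(sum(live) * n, sd = config$noise_sd_m), ncol = n)

    beta <- mToBeta(M)
    # constant near-boundary probes, written directly on the beta scale
    if (sum(is_bnd)) {
        lev <- rep(c(0.001, 0.999), length.out = sum(is_bnd))
        beta[is_bnd, ] <- matrix(lev, nrow = sum(is_bnd), ncol = n)
    }

    truth <- data.frame(probe_id = probe_id, archetype = archetype,
                        true_k = true_k, stringsAsFactors = FALSE)
    se <- methylExperiment(beta, sheet, probeData = truth)
    S4Vectors::metadata(se) <- list(config = config, genotypes = genotypes,
                                    slideShifts = shifts)
    se
}

#' Write a simulated study to disk as plain TSV files
#'
#' Emits `beta.tsv`, `samplesheet.tsv` and `truth.tsv` in the dialect read
#' back by [readBetaMatrix()] and [readSampleSheet()]; the round trip is
#' lossless to full double precision.
#'
#' @param se a `SummarizedExperiment` from [simulateStudy()].
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeStudy <- function(se, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("beta.tsv", "samplesheet.tsv", "truth.tsv"))
    writeBetaMatrix(SummarizedExperiment::assay(se, "beta"), paths[1L])
    writeSampleSheet(as.data.frame(SummarizedExperiment::colData(se)),
                     paths[2L])
    writeSampleSheet(as.data.frame(SummarizedExperiment::rowData(se)),
                     paths[3L])
    invisible(paths)
}
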