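#' Convert methylated/unmethylated signals to beta values
#'
#' beta = Meth / (Meth + Unmeth + offset). Cells where both signals are 0
#' (and offset is 0) yield `NA`; [shiftBetas()] later substitutes these
#' with beta = 0.5 so that M = 0.
#'
#' @param meth,unmeth numeric matrices of non-negative fluorescence
#'   intensities with identical dimensions (probes x samples). `NA`
#'   denotes missing.
#' @param offset non-negative constant added to the denominator. Default 0
#'   (the plain ratio); common pipelines use 100.
#' @return a beta matrix with the dimnames of `meth`.
#' @examples
#' signalsToBeta(matrix(100), matrix(300)) # 0.25
#' @export
signalsToBeta <- function(meth, unmeth, offset = 0) {
    if (!identical(dim(meth), dim(unmeth)))
        stop("meth and unmeth must have identical dimensions")
    if (length(offset) != 1L || is.na(offset) || offset < 0)
        stop("offset must be a single non-negative number")
    bad <- which(meth < 0 | unmeth < 0)
    if (length(bad)) {
        i <- bad[1L]
        stop(sprintf(
            "negative signal at row %d, column %d (meth=%g, unmeth=%g)",
            (i - 1L) %% nrow(meth) + 1L, (i - 1L) %/% nrow(meth) + 1L,
            meth[i], unmeth[i]))
    }
    denom <- meth + unmeth + offset
    beta <- meth / denom
    beta[!is.na(denom) & denom == 0] <- NA_real_
    beta
}

#' Logit2 transform: beta to M values
#'
#' M = log2(beta / (1 - beta)). Requires beta strictly inside (0, 1); run
#' [shiftBetas()] first if the matrix contains exact 0/1 or missing cells.
#'
#' @param beta numeric vector/matrix of beta values strictly in (0, 1).
#' @return M values, same shape.
#' @examples
#' betaToM(0.8) # log2(4) = 2
#' @export
betaToM <- function(beta) {
    v <- beta[!is.na(beta)]
    if (any(v <= 0 | v >= 1))
        stop("beta values must lie strictly in (0, 1); ",
             "apply shiftBetas() to handle exact 0/1 and missing cells")
    log2(beta) - log2(1 - beta)
}

#' Inverse logit2 transform: M to beta values
#'
#' beta = 2^M / (1 + 2^M), evaluated in a numerically stable form so that
#' very large |M| saturates towards 0/1 without overflow or NaN.
#'
#' @param m numeric vector/matrix of finite M values.
#' @return beta values strictly in (0, 1) up to double precision, same
#'   shape.
#' @examples
#' mToBeta(0)    # 0.5
#' mToBeta(-1000) # underflows to 0 smoothly, never NaN
#' @export
mToBeta <- function(m) {
    # plogis is the stable logistic CDF; logit2 is logit on the log-2 scale
    stats::plogis(m * log(2))
}

#' Prepare a beta matrix for the M-value transform
#'
#' Edge-case preprocessing applied before logit transformation: missing
#' cells (e.g. both signals zero) become beta = 0.5 (M = 0); exact 0
#' becomes `eps` and exact 1 becomes `1 - eps`. Probes that are then
#' constant across all samples receive a very small amount of Gaussian
#' noise (default sd 1e-8), because zero-variance features abort
#' empirical-Bayes correction; noisy values are re-clipped into
#' `[eps, 1 - eps]`.
#'
#' @param beta numeric matrix of beta values (probes x samples); values in
#'   `[0, 1]` or `NA`.
#' @param eps boundary shift, in (0, 0.5). Default 1e-4 keeps |M| below 14.
#' @param noise_sd standard deviation of the noise injected into
#'   zero-variance probes; default 1e-8. Set 0 to disable (then the call is
#'   idempotent).
#' @param seed RNG seed, required when `noise_sd > 0`.
#' @return a beta matrix with no 0, 1 or missing values.
#' @examples
#' shiftBetas(matrix(c(0, NA, 0.3, 1), 2), noise_sd = 0)
#' @export
shiftBetas <- function(beta, eps = 1e-4, noise_sd = 1e-8, seed = NULL) {
    if (length(eps) != 1L || is.na(eps) || eps <= 0 || eps >= 0.5)
        stop("eps must lie in (0, 0.5)")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (noise_sd > 0 && is.null(seed))
        stop("seed is required when noise_sd > 0")
    beta <- as.matrix(beta)
    if (any(beta < 0 | beta > 1, na.rm = TRUE))
        stop("beta values must lie in [0, 1]")
    # missing substitution first, so constant-at-0.5 probes are seen by the
    # zero-variance rule below
    beta[is.na(beta)] <- 0.5
    beta[beta == 0] <- eps
    beta[beta == 1] <- 1 - eps
    flat <- apply(beta, 1L, min) == apply(beta, 1L, max)
    if (any(flat) && noise_sd > 0) {
        set.seed(seed)
        n <- ncol(beta)
        noise <- matrix(rnorm(sum(flat) * n, sd = noise_sd), ncol = n)
        beta[flat, ] <- beta[flat, , drop = FALSE] + noise
        beta[beta < eps] <- eps
        beta[beta > 1 - eps] <- 1 - eps
    }
    beta
}
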