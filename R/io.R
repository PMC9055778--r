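#' Read / write delimited methylation matrices and sample sheets
#'
#' The on-disk dialect is plain TSV (or CSV): the matrix has probe ids in
#' the first column and sample ids in the header row; missing values are
#' empty fields or `NA`. Sample sheets are one row per sample with a
#' `sample_id` column.
#'
#' @param path file path.
#' @param sep field separator, `"\t"` by default.
#' @return `readBetaMatrix()`: a numeric matrix with probe row names and
#'   sample column names. `readSampleSheet()`: a `data.frame`.
#' @export
readBetaMatrix <- function(path, sep = "\t") {
    df <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                     check.names = FALSE, na.strings = c("", "NA"))
    as.matrix(df)
}

#' @rdname readBetaMatrix
#' @param x matrix (for `writeBetaMatrix`) or data.frame (for
#'   `writeSampleSheet`).
#' @param digits significant digits for numeric output; `NA` writes full
#'   precision.
#' @export
writeBetaMatrix <- function(x, path, sep = "\t", digits = NA) {
    out <- x
    if (!is.na(digits)) out <- signif(out, digits)
    df <- data.frame(probe_id = rownames(out), out,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readBetaMatrix
#' @export
readSampleSheet <- function(path, sep = "\t") {
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

#' @rdname readBetaMatrix
#' @export
writeSampleSheet <- function(x, path, sep = "\t") {
    write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Bundle a beta matrix and sample sheet into a SummarizedExperiment
#'
#' The package's study container is a plain
#' [SummarizedExperiment::SummarizedExperiment] with a `beta` assay,
#' the sample sheet as `colData` and optional probe annotation (or
#' simulation ground truth) as `rowData`.
#'
#' @param beta probes x samples beta matrix with dimnames.
#' @param sampleSheet data.frame with a `sample_id` column matching the
#'   matrix columns.
#' @param probeData optional data.frame of per-probe annotation, rows
#'   matching the matrix rows.
#' @return a `SummarizedExperiment`.
#' @export
methylExperiment <- function(beta, sampleSheet, probeData = NULL) {
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("beta must carry probe rownames and sample colnames")
    if (!"sample_id" %in% names(sampleSheet))
        stop("sampleSheet must have a 'sample_id' column")
    if (!identical(as.character(sampleSheet$sample_id), colnames(beta)))
        sampleSheet <-
            sampleSheet[match(colnames(beta), sampleSheet$sample_id), ]
    if (anyNA(sampleSheet$sample_id))
        stop("sampleSheet is missing entries for some matrix columns")
    cd <- S4Vectors::DataFrame(sampleSheet, row.names = colnames(beta))
    args <- list(assays = list(beta = beta), colData = cd)
    if (!is.null(probeData))
        args$rowData <- S4Vectors::DataFrame(probeData,
                                             row.names = rownames(beta))
    do.call(SummarizedExperiment::SummarizedExperiment, args)
}
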