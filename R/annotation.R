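# Unified nearest-neighbour DNA/DNA duplex parameters
# (Allawi & SantaLucia): stack enthalpies in kcal/mol and entropies in
# cal/(mol K), plus initiation terms for terminal G.C and A.T pairs.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
.NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbour melting temperature of a DNA duplex
#'
#' Tm of the probe sequence bound to its perfect complement, from summed
#' nearest-neighbour stack enthalpies/entropies plus initiation terms:
#' `Tm = dH / (dS + R ln(C_T / 4)) - 273.15`. No correction for mono- or
#' divalent cation concentration is applied, so absolute values are
#' comparable only within a fixed parameter/concentration choice.
#'
#' @param sequence DNA string over A/C/G/T, length >= 8 (degenerate R
#'   bases must be resolved first, see [probeTm()]). Case-insensitive.
#' @param ct total strand concentration in mol/L (default 0.25 uM).
#' @return melting temperature in degrees Celsius.
#' @examples
#' nnTm("ACGTACGTACGTACGT")
#' @export
nnTm <- function(sequence, ct = 0.25e-6) {
    s <- toupper(sequence)
    if (nchar(s) < 8) stop("sequence must be at least 8 nt")
    b <- strsplit(s, "")[[1]]
    if (!all(b %in% c("A", "C", "G", "T")))
        stop("sequence may only contain A/C/G/T ",
             "(resolve degenerate R bases first)")
    stacks <- paste0(b[-length(b)], b[-1])
    dh <- sum(.NN_DH[stacks])
    ds <- sum(.NN_DS[stacks])
    ends <- ifelse(b[c(1, length(b))] %in% c("G", "C"), "GC", "AT")
    dh <- dh + sum(.NN_INIT_DH[ends])
    ds <- ds + sum(.NN_INIT_DS[ends])
    R <- 1.9872 # cal/(mol K)
    dh * 1000 / (ds + R * log(ct / 4)) - 273.15
}

#' Melting temperature of an Infinium probe record
#'
#' Type I designs carry an A probe and a B probe: both Tms are computed
#' and averaged. Type II designs carry degenerate R (purine) bases at
#' internal CpG cytosine-opposite positions: the Tm is the mean of the
#' all-R-to-A and all-R-to-G substituted sequences.
#'
#' @param sequences character vector: two sequences (A and B probes) for
#'   Type I, one sequence (possibly containing R) for Type II.
#' @param type `"I"` or `"II"`.
#' @param ct passed to [nnTm()].
#' @return probe Tm in degrees Celsius.
#' @export
probeTm <- function(sequences, type = c("II", "I"), ct = 0.25e-6) {
    type <- match.arg(type)
    if (type == "I") {
        if (length(sequences) != 2)
            stop("Type I records need the A and B probe sequences")
        return(mean(vapply(sequences, nnTm, numeric(1), ct = ct)))
    }
    if (length(sequences) != 1)
        stop("Type II records carry a single sequence")
    s <- toupper(sequences)
    mean(c(nnTm(gsub("R", "A", s), ct), nnTm(gsub("R", "G", s), ct)))
}

#' Count CpG sites internal to a probe sequence
#'
#' Counts CG dinucleotides; a degenerate R base standing in at the
#' position opposite a CpG cytosine is treated as a potential G, so CR is
#' also counted as a (degenerate) CpG.
#'
#' @param sequence DNA string over A/C/G/T/R.
#' @return integer count.
#' @examples
#' internalCpgCount("ACGTACGT") # 2
#' internalCpgCount("ACRT")     # 1
#' @export
internalCpgCount <- function(sequence) {
    s <- toupper(sequence)
    if (grepl("[^ACGTR]", s)) stop("sequence may only contain A/C/G/T/R")
    b <- strsplit(s, "")[[1]]
    if (length(b) < 2) return(0L)
    pair <- paste0(b[-length(b)], b[-1])
    sum(pair %in% c("CG", "CR"))
}
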