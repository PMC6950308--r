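# IUPAC residue masses (Da). Monoisotopic < average for every residue.
.AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

.AA_AVG <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
             V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
             I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
             K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
             F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

.WATER_MONO <- 18.01056
.WATER_AVG <- 18.0153
# proton mass, not atomic hydrogen: charge carriers are protons
.PROTON <- 1.00728
.H_AVG <- 1.008
.CO_MONO <- 27.99491
.NH3_MONO <- 17.02655

#' Amino-acid residue mass table
#'
#' Monoisotopic and average residue masses (Da) of the 20 standard amino
#' acids, plus the water and proton constants used throughout the package.
#'
#' @return A data.frame with columns \code{residue}, \code{mono}, \code{avg},
#'   carrying attributes \code{water_mono}, \code{water_avg}, \code{proton}.
#' @examples
#' head(aminoAcidMasses())
#' @export
aminoAcidMasses <- function() {
    out <- data.frame(residue = names(.AA_MONO), mono = unname(.AA_MONO),
                      avg = unname(.AA_AVG), stringsAsFactors = FALSE)
    attr(out, "water_mono") <- .WATER_MONO
    attr(out, "water_avg") <- .WATER_AVG
    attr(out, "proton") <- .PROTON
    out
}

#' Carbamidomethyl-cysteine modification
#'
#' Fixed modification produced by iodoacetamide alkylation of reduced
#' cysteines: +57.02146 Da monoisotopic (+57.0513 average) per Cys.
#'
#' @return A [ModificationSpec-class] object targeting \code{C}.
#' @examples
#' modCAM()
#' @export
modCAM <- function() {
    new("ModificationSpec", name = "carbamidomethyl", deltaMono = 57.02146,
        deltaAvg = 57.0513, targets = "C")
}

#' Construct a peptide ion
#'
#' @param sequence one-letter residue string.
#' @param mods list of [ModificationSpec-class] objects (fixed mods).
#' @param charge positive integer charge state.
#' @param start,end optional 1-based inclusive coordinates on the parent.
#' @return A [PeptideIon-class] object.
#' @examples
#' PeptideIon("DANSFCQLPAVVGK", mods = list(modCAM()), charge = 2)
#' @export
PeptideIon <- function(sequence, mods = list(), charge = 1L,
                       start = NA_integer_, end = NA_integer_) {
    if (is(mods, "ModificationSpec")) mods <- list(mods)
    new("PeptideIon", sequence = sequence, mods = mods,
        charge = as.integer(charge), start = as.integer(start),
        end = as.integer(end))
}

#' @rdname accessors
#' @export
setMethod("peptideSequence", "PeptideIon", function(x) x@sequence)

setMethod("show", "PeptideIon", function(object) {
    pos <- if (!is.na(object@start))
        sprintf(" [%d-%d]", object@start, object@end) else ""
    mods <- if (length(object@mods))
        paste0(" + ", paste(vapply(object@mods, function(m) m@name, ""),
                            collapse = ", ")) else ""
    cat(sprintf("PeptideIon %s%s (z=%d)%s\n", object@sequence, pos,
                object@charge, mods))
})

setMethod("show", "ModificationSpec", function(object) {
    cat(sprintf("ModificationSpec '%s': %+0.5f Da mono (%+0.4f avg) on %s\n",
                object@name, object@deltaMono, object@deltaAvg,
                paste(object@targets, collapse = ",")))
})

.residues <- function(seq) {
    r <- strsplit(seq, "")[[1]]
    bad <- setdiff(r, names(.AA_MONO))
    if (length(bad))
        stop(sprintf("unknown residue code(s): %s",
                     paste(unique(bad), collapse = ", ")), call. = FALSE)
    r
}

.modDelta <- function(residues, mods, type) {
    if (!length(mods)) return(0)
    sum(vapply(mods, function(m) {
        d <- if (type == "mono") m@deltaMono else m@deltaAvg
        d * sum(residues %in% m@targets)
    }, numeric(1)))
}

#' Neutral peptide masses
#'
#' Monoisotopic or average neutral mass of a linear peptide: sum of residue
#' masses plus one water, plus fixed-modification deltas for every matching
#' residue.
#'
#' @param seq one-letter residue string (or a [PeptideIon-class], whose
#'   sequence and mods are then used).
#' @param mods list of [ModificationSpec-class] objects.
#' @return Mass in Da.
#' @examples
#' peptideMonoMass("YYYNTEAGK")
#' peptideMonoMass("NNFETVEDCR", mods = list(modCAM()))
#' peptideAvgMass("A")
#' @export
peptideMonoMass <- function(seq, mods = list()) {
    if (is(seq, "PeptideIon")) { mods <- seq@mods; seq <- seq@sequence }
    r <- .residues(seq)
    sum(.AA_MONO[r]) + .WATER_MONO + .modDelta(r, mods, "mono")
}

#' @rdname peptideMonoMass
#' @export
peptideAvgMass <- function(seq, mods = list()) {
    if (is(seq, "PeptideIon")) { mods <- seq@mods; seq <- seq@sequence }
    r <- .residues(seq)
    sum(.AA_AVG[r]) + .WATER_AVG + .modDelta(r, mods, "avg")
}

#' m/z of a charged ion
#'
#' \code{(M + z * 1.00728) / z} for a neutral mass M and charge z, the proton
#' being the charge carrier in positive electrospray mode.
#'
#' @param neutralMass neutral mass in Da.
#' @param charge positive integer charge.
#' @return m/z in Th.
#' @examples
#' ionMz(peptideMonoMass("DANSFCQLPAVVGK", list(modCAM())), 2)
#' @export
ionMz <- function(neutralMass, charge) {
    charge <- as.integer(charge)
    if (any(charge <= 0L)) stop("charge must be >= 1", call. = FALSE)
    (neutralMass + charge * .PROTON) / charge
}

#' m/z of a peptide ion at its charge state
#'
#' Convenience wrapper: monoisotopic neutral mass of the (modified) peptide,
#' then [ionMz()] at the ion's charge.
#'
#' @param peptide a [PeptideIon-class].
#' @return m/z in Th.
#' @export
peptideMz <- function(peptide) {
    stopifnot(is(peptide, "PeptideIon"))
    ionMz(peptideMonoMass(peptide), peptide@charge)
}

#' Average mass of a full-length chain
#'
#' Average (isotope-averaged) mass of an intact chain, either fully reduced
#' or with a given number of disulfide bonds (each disulfide removes two
#' hydrogens: \eqn{-2 \times 1.008} Da average).
#'
#' @param seq one-letter residue string.
#' @param disulfides number of disulfide bonds (0 = reduced linear chain).
#' @param mods fixed modifications, if any (reduced/alkylated chains).
#' @return Mass in Da.
#' @examples
#' chainAverageMass("ACCA", disulfides = 1)
#' @export
chainAverageMass <- function(seq, disulfides = 0, mods = list()) {
    r <- .residues(seq)
    nCys <- sum(r == "C")
    if (2 * disulfides > nCys)
        stop(sprintf("%d disulfides require %d Cys; sequence has %d",
                     disulfides, 2 * disulfides, nCys), call. = FALSE)
    peptideAvgMass(seq, mods) - disulfides * 2 * .H_AVG
}

#' Round half-up at a given number of decimals
#'
#' Presentation-layer rounding used when comparing computed masses with
#' printed 2-decimal values (base \code{round()} rounds half-to-even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}
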