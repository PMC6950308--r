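#' @import methods
NULL

#' Fixed peptide modification
#'
#' Describes a fixed (non-variable) chemical modification applied to every
#' occurrence of its target residues, e.g. carbamidomethylation of cysteine
#' after iodoacetamide alkylation.
#'
#' @slot name modification name.
#' @slot deltaMono monoisotopic mass shift (Da).
#' @slot deltaAvg average mass shift (Da).
#' @slot targets one-letter codes of the residues carrying the modification.
#'
#' @seealso [modCAM()] for the standard carbamidomethyl-cysteine spec.
#' @exportClass ModificationSpec
setClass("ModificationSpec",
    representation(name = "character", deltaMono = "numeric",
                   deltaAvg = "numeric", targets = "character"))

setValidity("ModificationSpec", function(object) {
    if (length(object@targets) < 1L)
        return("'targets' must name at least one residue")
    if (length(object@deltaMono) != 1L || length(object@deltaAvg) != 1L)
        return("mass deltas must be scalar")
    TRUE
})

#' Peptide ion
#'
#' A (sub)sequence with its fixed modifications and charge state: the unit of
#' all mass arithmetic in the package. Positions, when set, are 1-based
#' inclusive coordinates on the parent chain.
#'
#' @slot sequence one-letter residue string.
#' @slot mods list of [ModificationSpec-class] objects.
#' @slot charge positive integer charge state.
#' @slot start,end 1-based inclusive coordinates on the parent (NA if unset).
#'
#' @exportClass PeptideIon
setClass("PeptideIon",
    representation(sequence = "character", mods = "list",
                   charge = "integer", start = "integer", end = "integer"),
    prototype(mods = list(), charge = 1L, start = NA_integer_,
              end = NA_integer_))

setValidity("PeptideIon", function(object) {
    bad <- setdiff(strsplit(object@sequence, "")[[1]], names(.AA_MONO))
    if (length(bad))
        return(sprintf("unknown residue code(s): %s",
                       paste(unique(bad), collapse = ", ")))
    if (object@charge < 1L) return("charge must be >= 1")
    if (!is.na(object@start) && !is.na(object@end) &&
        object@end - object@start + 1L != nchar(object@sequence))
        return("end - start + 1 must equal sequence length")
    TRUE
})

#' Centroided MS/MS spectrum
#'
#' Precursor m/z and charge plus a centroided fragment peak list, sorted
#' ascending by m/z.
#'
#' @slot mz fragment m/z values (Th), ascending.
#' @slot intensity fragment intensities (arbitrary units), non-negative.
#' @slot precursorMz precursor m/z (Th).
#' @slot precursorCharge precursor charge state.
#' @slot id spectrum title/identifier.
#'
#' @exportClass Spectrum
setClass("Spectrum",
    representation(mz = "numeric", intensity = "numeric",
                   precursorMz = "numeric", precursorCharge = "integer",
                   id = "character"))

setValidity("Spectrum", function(object) {
    if (length(object@mz) != length(object@intensity))
        return("mz and intensity lengths differ")
    if (is.unsorted(object@mz)) return("peaks must be sorted by m/z")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    if (object@precursorCharge < 1L) return("precursor charge must be >= 1")
    TRUE
})

#' De novo sequence tag
#'
#' A short partial sequence read from same-series product-ion spacings. Each
#' position is a residue ambiguity class (a set of residues indistinguishable
#' at the working tolerance, e.g. I/L).
#'
#' @slot classes list of character vectors, one residue class per position.
#' @slot anchorMzLow,anchorMzHigh m/z of the first and last supporting peak.
#' @slot direction \code{"b"} (reads N-to-C) or \code{"y"} (reads C-to-N).
#'
#' @exportClass SequenceTag
setClass("SequenceTag",
    representation(classes = "list", anchorMzLow = "numeric",
                   anchorMzHigh = "numeric", direction = "character"))

setValidity("SequenceTag", function(object) {
    if (length(object@classes) < 1L) return("tag must have length >= 1")
    if (any(vapply(object@classes, length, 1L) < 1L))
        return("every residue class must be non-empty")
    if (!object@direction %in% c("b", "y"))
        return("direction must be 'b' or 'y'")
    TRUE
})

#' Candidate protein with peptide-level evidence
#'
#' A translated transcriptome sequence together with the observed precursors
#' it explains: matched theoretical tryptic peptides, per-match m/z errors and
#' the resulting residue coverage.
#'
#' @slot transcriptId source transcript identifier (with reading frame).
#' @slot sequence candidate protein sequence.
#' @slot matches data.frame with columns \code{sequence, start, end, missed,
#'   charge, theoMz, obsMz, deltaMz}.
#' @slot coverage fraction of residues covered by matched peptides, in [0,1].
#'
#' @exportClass CandidateProtein
setClass("CandidateProtein",
    representation(transcriptId = "character", sequence = "character",
                   matches = "data.frame", coverage = "numeric"))

setValidity("CandidateProtein", function(object) {
    if (object@coverage < 0 || object@coverage > 1)
        return("coverage must lie in [0, 1]")
    TRUE
})

#' Tight-binding inhibition assay
#'
#' A concentration/rate table for a protease inhibition experiment together
#' with the enzyme, substrate and Km context needed to convert the apparent
#' inhibition constant into Ki.
#'
#' @slot enzymeNM active-site-titrated enzyme concentration (nM).
#' @slot substrateUM substrate concentration (uM).
#' @slot kmUM substrate Km (uM).
#' @slot inhibitorNM inhibitor concentrations (nM).
#' @slot rate observed rates (e.g. delta-OD405/min), parallel to inhibitorNM.
#' @slot v0 uninhibited rate, same units as \code{rate}.
#' @slot replicates replicate count the rates are averaged over.
#'
#' @exportClass InhibitionAssay
setClass("InhibitionAssay",
    representation(enzymeNM = "numeric", substrateUM = "numeric",
                   kmUM = "numeric", inhibitorNM = "numeric",
                   rate = "numeric", v0 = "numeric", replicates = "integer"),
    prototype(replicates = 1L))

setValidity("InhibitionAssay", function(object) {
    if (length(object@inhibitorNM) != length(object@rate))
        return("inhibitorNM and rate lengths differ")
    if (any(c(object@enzymeNM, object@substrateUM, object@kmUM,
              object@inhibitorNM) < 0))
        return("concentrations must be >= 0")
    if (object@v0 <= 0) return("v0 must be > 0")
    TRUE
})

#' Fitted tight-binding inhibition constant
#'
#' Result of a Morrison-equation fit: apparent and substrate-corrected Ki
#' with standard errors, residuals and a convergence flag.
#'
#' @slot ki,kiSE substrate-corrected inhibition constant and SE (nM).
#' @slot kiApp,kiAppSE apparent inhibition constant and SE (nM).
#' @slot residuals fit residuals on the fractional-activity scale.
#' @slot converged logical convergence flag.
#'
#' @exportClass KineticFit
setClass("KineticFit",
    representation(ki = "numeric", kiSE = "numeric", kiApp = "numeric",
                   kiAppSE = "numeric", residuals = "numeric",
                   converged = "logical"))

setValidity("KineticFit", function(object) {
    if (object@converged && (is.na(object@ki) || object@ki <= 0))
        return("a converged fit must report ki > 0")
    TRUE
})

#' Per-column conservation profile
#'
#' Column-wise physico-chemical conservation scores (0-11) of a multiple
#' alignment, with the underlying residue columns retained for inspection.
#'
#' @slot scores integer scores in 0..11, one per alignment column.
#' @slot columns list of character vectors (the residues in each column,
#'   gaps as \code{"-"}).
#'
#' @exportClass ConservationProfile
setClass("ConservationProfile",
    representation(scores = "integer", columns = "list"))

setValidity("ConservationProfile", function(object) {
    if (length(object@scores) != length(object@columns))
        return("scores and columns lengths differ")
    if (length(object@scores) && (min(object@scores) < 0L ||
                                  max(object@scores) > 11L))
        return("scores must lie in 0..11")
    TRUE
})

#' Molecular-dynamics trajectory
#'
#' Frames-by-atoms coordinate sets (Angstrom) with per-atom residue metadata.
#'
#' @slot coords numeric array of dimension frames x atoms x 3.
#' @slot atoms data.frame with columns \code{name, element, resno, resname,
#'   chain} (one row per atom; residue numbers are 1-based file numbering).
#' @slot frameTimeNs time per frame in ns (NA if unknown).
#'
#' @exportClass Trajectory
setClass("Trajectory",
    representation(coords = "array", atoms = "data.frame",
                   frameTimeNs = "numeric"),
    prototype(frameTimeNs = NA_real_))

setValidity("Trajectory", function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[3] != 3L)
        return("coords must be a frames x atoms x 3 array")
    if (d[2] != nrow(object@atoms))
        return("atom count mismatch between coords and atoms table")
    if (any(!is.finite(object@coords)))
        return("coordinates must be finite")
    need <- c("name", "element", "resno", "resname", "chain")
    if (!all(need %in% names(object@atoms)))
        return(sprintf("atoms table must have columns: %s",
                       paste(need, collapse = ", ")))
    TRUE
})
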