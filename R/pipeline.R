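#' Read and write FASTA
#'
#' Thin wrappers over Biostrings for nucleotide and protein FASTA.
#'
#' @param path file path.
#' @param type \code{"AA"} or \code{"DNA"}.
#' @return \code{readFasta} returns a named character vector.
#' @export
readFasta <- function(path, type = c("AA", "DNA")) {
    type <- match.arg(type)
    x <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- names(x)
    out
}

#' @rdname readFasta
#' @param seqs named character vector of sequences.
#' @export
writeFasta <- function(seqs, path, type = c("AA", "DNA")) {
    type <- match.arg(type)
    x <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' End-to-end MS identification of a protein from spectra and a transcriptome
#'
#' Chains the MS/MS stages: sequence tags are deduced from every spectrum,
#' searched against the six-frame-translated transcriptome, and each
#' candidate protein hit by a tag is verified against the observed
#' precursors; the best-covered candidate above \code{minCoverage} is
#' reconstructed from its matched peptides and its intact average mass
#' reported.
#'
#' @param spectra list of [Spectrum-class] objects (or an MGF path).
#' @param transcriptome named character vector of contigs (or a nucleotide
#'   FASTA path).
#' @param fragmentTol fragment/spacing tolerance (Th).
#' @param precursorTol precursor matching tolerance (Th).
#' @param minTagLen minimum tag length.
#' @param mods fixed modifications.
#' @param minCoverage minimum residue coverage for an identification.
#' @param minCandidateLength minimum candidate protein length (aa).
#' @return list with \code{identified} flag and, when identified,
#'   \code{candidate} ([CandidateProtein-class]), \code{reconstruction}
#'   (from [reconstructSequence()]), \code{nTags}, \code{hits} (tag-hit
#'   table), \code{uniqueProtein} (TRUE when long tags hit one protein
#'   only).
#' @export
runIdentification <- function(spectra, transcriptome, fragmentTol = 0.3,
                              precursorTol = 0.5, minTagLen = 4,
                              mods = list(modCAM()), minCoverage = 0.5,
                              minCandidateLength = 20) {
    if (is.character(spectra) && length(spectra) == 1L)
        spectra <- readMGF(spectra)
    if (is.character(transcriptome) && length(transcriptome) == 1L &&
        file.exists(transcriptome))
        transcriptome <- readFasta(transcriptome, type = "DNA")
    none <- list(identified = FALSE, candidate = NULL,
                 reconstruction = NULL, nTags = 0L,
                 hits = data.frame(), uniqueProtein = NA)
    if (!length(spectra)) return(none)
    tags <- unlist(lapply(spectra, deduceTags, tol = fragmentTol,
                          minTagLen = minTagLen, mods = mods),
                   recursive = FALSE)
    tags <- tags[!duplicated(vapply(tags, tagString, ""))]
    if (!length(tags)) return(none)
    proteins <- candidateProteins(transcriptome,
                                  minLength = minCandidateLength)
    hits <- searchTags(proteins, tags)
    none$nTags <- length(tags)
    if (!nrow(hits)) return(none)
    # unique identification: some informative (>= 6 residue) tag hits
    # exactly one protein
    long <- hits[hits$length >= 6L, , drop = FALSE]
    perTag <- tapply(long$proteinId, long$tag,
                     function(p) unique(p))
    uniqueTags <- names(perTag)[vapply(perTag, length, 1L) == 1L]
    uniqueProtein <- length(uniqueTags) > 0L
    precursors <- data.frame(
        mz = vapply(spectra, precursorMz, numeric(1)),
        charge = vapply(spectra, precursorCharge, integer(1)))
    cands <- unique(hits$proteinId)
    verified <- lapply(cands, function(id)
        verifyCandidate(proteins[[id]], precursors, tol = precursorTol,
                        mods = mods, id = id))
    cov <- vapply(verified, residueCoverage, numeric(1))
    best <- verified[[which.max(cov)]]
    uniqueProtein <- uniqueProtein &&
        best@transcriptId %in% unlist(perTag[uniqueTags])
    if (max(cov) < minCoverage) {
        none$hits <- hits
        none$uniqueProtein <- uniqueProtein
        return(none)
    }
    rec <- reconstructSequence(matchedPeptides(best),
                               parentLength = nchar(best@sequence))
    list(identified = TRUE, candidate = best, reconstruction = rec,
         nTags = length(tags), hits = hits, uniqueProtein = uniqueProtein)
}

.fileHash <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        unname(tools::md5sum(x)) else NA_character_
}

#' Combined characterization report
#'
#' Dispatches to the kinetics, conservation/stability and trajectory stages
#' for whichever inputs are supplied and merges the results into one report
#' with the parameters echoed. Stage failures are isolated into an
#' \code{errors} section rather than aborting the run.
#'
#' @param assay an [InhibitionAssay-class] (optional).
#' @param alignment named character vector of aligned sequences (or aligned
#'   FASTA path; optional).
#' @param ddg ddG data.frame with columns \code{homolog, position, ddg}
#'   (optional; requires \code{alignment}).
#' @param trajectory a [Trajectory-class] (or multi-model PDB path;
#'   optional).
#' @param hbondDCut,hbondACut H-bond criteria passed to [hbondOccupancy()].
#' @param contactCutoff cutoff passed to [closeContacts()].
#' @param intermolecular analyze inter-chain interactions in the trajectory.
#' @return list with sections \code{kinetics}, \code{conservation},
#'   \code{stability}, \code{trajectory}, \code{provenance}, \code{errors}
#'   (only the sections whose inputs were supplied are present).
#' @export
runCharacterization <- function(assay = NULL, alignment = NULL, ddg = NULL,
                                trajectory = NULL, hbondDCut = 3.5,
                                hbondACut = 150, contactCutoff = 4.0,
                                intermolecular = TRUE) {
    report <- list(provenance = list(
        package = as.character(utils::packageVersion("KunitzChar")),
        parameters = list(hbondDCut = hbondDCut, hbondACut = hbondACut,
                          contactCutoff = contactCutoff),
        inputHashes = list(alignment = .fileHash(alignment),
                           trajectory = .fileHash(trajectory))))
    errors <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            errors[[name]] <<- conditionMessage(e)
            NULL
        })
    }
    if (!is.null(assay)) {
        report$kinetics <- stage("kinetics", {
            fit <- fitKi(assay)
            list(fit = fit,
                 residualActivityPct = residualActivity(assay@rate,
                                                        assay@v0))
        })
    }
    if (!is.null(alignment)) {
        if (is.character(alignment) && length(alignment) == 1L &&
            file.exists(alignment))
            alignment <- readFasta(alignment, type = "AA")
        report$conservation <- stage("conservation", {
            prof <- scoreAlignment(alignment)
            list(profile = prof, histogram = scoreHistogram(prof),
                 bins = binScores(prof))
        })
        if (!is.null(ddg)) {
            report$stability <- stage("stability", {
                md <- meanDdgPerColumn(ddg, alignment)
                reg <- conservationStabilityRegression(
                    scoreAlignment(alignment), md)
                list(meanDdg = md, regression = reg)
            })
        }
    }
    if (!is.null(trajectory)) {
        if (is.character(trajectory) && length(trajectory) == 1L)
            trajectory <- readTrajectoryPDB(trajectory)
        report$trajectory <- stage("trajectory", {
            aligned <- superposeFrames(trajectory)
            list(rmsf = rmsf(aligned),
                 hbonds = hbondOccupancy(aligned, dCut = hbondDCut,
                                         aCut = hbondACut,
                                         intermolecular = intermolecular),
                 contacts = closeContacts(aligned, cutoff = contactCutoff,
                                          intermolecular = intermolecular))
        })
    }
    report$errors <- errors
    report
}
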