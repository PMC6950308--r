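#' Six-frame translation
#'
#' Standard-code translation of the three forward and three
#' reverse-complement reading frames of a nucleotide sequence. Stop codons
#' are rendered as \code{*}; codons containing \code{N} translate to
#' \code{X}.
#'
#' @param nt nucleotide sequence over \code{A, C, G, T, N}.
#' @return Named character vector of 6 protein strings
#'   (\code{F1, F2, F3, R1, R2, R3}).
#' @examples
#' sixFrameTranslate("ATGGGT")
#' @export
sixFrameTranslate <- function(nt) {
    nt <- toupper(nt)
    bad <- setdiff(strsplit(nt, "")[[1]], c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop(sprintf("non-IUPAC nucleotide(s): %s",
                     paste(unique(bad), collapse = ", ")), call. = FALSE)
    vapply(.sixFrameSet(nt), `[`, "", 1L)
}

# vectorized six-frame translation of a set of contigs: one translate()
# call per frame, not per contig
.sixFrameSet <- function(contigs) {
    x <- Biostrings::DNAStringSet(contigs)
    rc <- Biostrings::reverseComplement(x)
    out <- list()
    for (strand in c("F", "R")) {
        s <- if (strand == "F") x else rc
        for (off in 0:2) {
            w <- (Biostrings::width(s) - off) %/% 3L * 3L
            keep <- w >= 3L
            aa <- rep("", length(s))
            if (any(keep))
                aa[keep] <- as.character(Biostrings::translate(
                    Biostrings::subseq(s[keep], off + 1L, off + w[keep]),
                    if.fuzzy.codon = "X"))
            out[[paste0(strand, off + 1L)]] <- aa
        }
    }
    out
}

#' Candidate proteins from a transcriptome
#'
#' Six-frame translates every contig and splits each frame at stop codons.
#' Segments shorter than \code{minLength} residues (or containing \code{X})
#' are discarded before digest verification.
#'
#' @param contigs named character vector of nucleotide sequences, or a
#'   \code{Biostrings::DNAStringSet}.
#' @param minLength minimum candidate length in residues.
#' @return Named character vector of candidate protein sequences; names are
#'   \code{<contig>|<frame>|<segment>}.
#' @export
candidateProteins <- function(contigs, minLength = 20) {
    if (is(contigs, "DNAStringSet")) {
        nm <- names(contigs)
        contigs <- as.character(contigs)
        names(contigs) <- nm
    }
    if (is.null(names(contigs)))
        names(contigs) <- paste0("contig", seq_along(contigs))
    frames <- .sixFrameSet(contigs)
    out <- character()
    for (f in names(frames)) {
        segList <- strsplit(frames[[f]], "*", fixed = TRUE)
        for (i in seq_along(contigs)) {
            segs <- segList[[i]]
            keep <- nchar(segs) >= minLength & !grepl("X", segs, fixed = TRUE)
            segs <- segs[keep]
            if (length(segs))
                out[paste(names(contigs)[i], f, seq_along(segs),
                          sep = "|")] <- segs
        }
    }
    out
}

#' @rdname accessors
#' @export
setMethod("matchedPeptides", "CandidateProtein", function(x) x@matches)

#' @rdname accessors
#' @export
setMethod("residueCoverage", "CandidateProtein", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("peptideSequence", "CandidateProtein", function(x) x@sequence)

setMethod("show", "CandidateProtein", function(object) {
    cat(sprintf("CandidateProtein %s (%d aa): %d matched peptides, coverage %.2f\n",
                object@transcriptId, nchar(object@sequence),
                nrow(object@matches), object@coverage))
})

#' Verify a candidate protein against observed precursors
#'
#' Digests the candidate in silico, computes theoretical precursor m/z of
#' every product at the observed charge states, and matches each observed
#' precursor to at most one theoretical peptide within \code{tol} (ties
#' broken by smallest absolute m/z error, then by fewer missed cleavages).
#' Residue coverage is the union of matched peptide spans over the candidate
#' length.
#'
#' @param sequence candidate protein sequence.
#' @param precursors data.frame with columns \code{mz} and \code{charge}.
#' @param tol precursor matching tolerance in Th (m/z space).
#' @param mods fixed modifications (default carbamidomethyl-Cys).
#' @param maxMissed,minLength digestion parameters.
#' @param id candidate identifier carried into the result.
#' @return A [CandidateProtein-class].
#' @export
verifyCandidate <- function(sequence, precursors, tol = 0.5,
                            mods = list(modCAM()), maxMissed = 2,
                            minLength = 1, id = "candidate") {
    stopifnot(tol > 0)
    dig <- trypticDigest(sequence, maxMissed = maxMissed,
                         minLength = minLength)
    empty <- data.frame(sequence = character(), start = integer(),
                        end = integer(), missed = integer(),
                        charge = integer(), theoMz = numeric(),
                        obsMz = numeric(), deltaMz = numeric())
    if (!nrow(dig) || !nrow(precursors))
        return(new("CandidateProtein", transcriptId = id,
                   sequence = sequence, matches = empty, coverage = 0))
    mono <- vapply(dig$sequence, peptideMonoMass, numeric(1), mods = mods)
    rows <- list()
    for (i in seq_len(nrow(precursors))) {
        z <- precursors$charge[i]
        theo <- ionMz(mono, z)
        d <- theo - precursors$mz[i]
        ok <- which(abs(d) <= tol)
        if (!length(ok)) next
        ok <- ok[order(abs(d[ok]), dig$missed[ok])]
        b <- ok[1]
        rows[[length(rows) + 1L]] <- data.frame(
            sequence = dig$sequence[b], start = dig$start[b],
            end = dig$end[b], missed = dig$missed[b], charge = z,
            theoMz = theo[b], obsMz = precursors$mz[i],
            deltaMz = precursors$mz[i] - theo[b], stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(new("CandidateProtein", transcriptId = id,
                   sequence = sequence, matches = empty, coverage = 0))
    matches <- do.call(rbind, rows)
    rownames(matches) <- NULL
    covered <- IRanges::reduce(IRanges::IRanges(matches$start, matches$end))
    new("CandidateProtein", transcriptId = id, sequence = sequence,
        matches = matches,
        coverage = sum(IRanges::width(covered)) / nchar(sequence))
}

#' Assemble a full sequence from positioned peptides
#'
#' Overlap-assembles matched peptides (each carrying 1-based start/end
#' positions on the candidate) into the maximal contiguous covered sequence.
#' Conflicting residues at the same position raise an error naming the
#' position; uncovered positions are flagged as gaps. The average mass of the
#' assembled chain (reduced, unmodified Cys) is reported for comparison with
#' intact-mass measurement.
#'
#' @param peptides data.frame with columns \code{sequence, start, end}.
#' @param parentLength expected full-chain length, if known (positions beyond
#'   the assembly are then reported as unresolved).
#' @return list with \code{sequence} (maximal contiguous assembly),
#'   \code{start}, \code{end}, \code{unresolved} (integer positions),
#'   \code{avgMass}.
#' @export
reconstructSequence <- function(peptides, parentLength = NA) {
    stopifnot(nrow(peptides) >= 1)
    hi <- max(peptides$end, parentLength, na.rm = TRUE)
    filled <- rep(NA_character_, hi)
    for (i in seq_len(nrow(peptides))) {
        r <- strsplit(peptides$sequence[i], "")[[1]]
        idx <- peptides$start[i]:peptides$end[i]
        clash <- which(!is.na(filled[idx]) & filled[idx] != r)
        if (length(clash))
            stop(sprintf("conflicting residues at position %d ('%s' vs '%s')",
                         idx[clash[1]], filled[idx[clash[1]]], r[clash[1]]),
                 call. = FALSE)
        filled[idx] <- r
    }
    covered <- !is.na(filled)
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ci <- which(runs$values)
    best <- ci[which.max(runs$lengths[ci])]
    seq <- paste(filled[starts[best]:ends[best]], collapse = "")
    list(sequence = seq, start = starts[best], end = ends[best],
         unresolved = which(!covered), avgMass = chainAverageMass(seq))
}
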