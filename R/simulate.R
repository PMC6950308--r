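# Seeded generators for every input the workflow consumes. Defaults are the
# study conditions the analyses assume; each generator returns its ground
# truth alongside the data so round-trip tests need no external files.

.CODONS <- list(
    A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
    D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
    G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
    I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
    L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
    N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
    Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
    S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
    W = "TGG", Y = c("TAT", "TAC"))

.randomNt <- function(n, gc) {
    sample(c("A", "T", "G", "C"), n, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Simulate a transcriptome with one planted coding sequence
#'
#' Back-translates the planted protein with uniformly random synonymous
#' codons into one contig (random strand, random-length UTR flanks, stop
#' codon appended), plus decoy contigs of random nucleotides. Decoys are
#' rejection-sampled so that none of their six reading frames contains any
#' 8-mer of the planted protein.
#'
#' @param protein planted protein sequence.
#' @param nDecoys number of decoy contigs.
#' @param lengthRange decoy length range in nt.
#' @param gc decoy GC content.
#' @param seed RNG seed.
#' @return list with \code{contigs} (named character; the planted contig is
#'   shuffled in among the decoys) and \code{manifest} (planted contig id,
#'   strand, CDS offset, protein).
#' @export
simulateTranscriptome <- function(protein, nDecoys = 500,
                                  lengthRange = c(300, 3000), gc = 0.4,
                                  seed = 1) {
    set.seed(seed)
    res <- .residues(protein)
    cds <- paste(vapply(res, function(r) {
        cc <- .CODONS[[r]]
        cc[sample.int(length(cc), 1L)]
    }, ""), collapse = "")
    cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1L))
    # 5' UTR length a multiple of 3 and ending in an in-frame stop, so the
    # planted ORF segment is exactly the planted protein
    utr5 <- paste0(paste(.randomNt(3L * sample(16:99, 1L), gc),
                         collapse = ""), "TAA")
    utr3 <- paste(.randomNt(sample(50:300, 1L), gc), collapse = "")
    planted <- paste0(utr5, cds, utr3)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-")
        planted <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(planted)))
    kmers <- unique(substring(protein, seq_len(nchar(protein) - 7L),
                              8:nchar(protein)))
    decoys <- character(0)
    while (length(decoys) < nDecoys) {
        need <- nDecoys - length(decoys)
        cand <- vapply(sample(lengthRange[1]:lengthRange[2], need,
                              replace = TRUE), function(len)
            paste(.randomNt(len, gc), collapse = ""), "")
        frames <- .sixFrameSet(cand)
        joined <- do.call(paste, c(frames, sep = "#"))
        bad <- rep(FALSE, need)
        for (k in kmers) bad <- bad | grepl(k, joined, fixed = TRUE)
        decoys <- c(decoys, cand[!bad])
    }
    contigs <- c(decoys, planted)
    ord <- sample.int(length(contigs))
    contigs <- contigs[ord]
    names(contigs) <- sprintf("transcript%04d", seq_along(contigs))
    plantedId <- names(contigs)[which(ord == length(decoys) + 1L)]
    list(contigs = contigs,
         manifest = list(plantedId = plantedId, strand = strand,
                         cdsOffsetNt = nchar(utr5), protein = protein))
}

#' Precursor charge model
#'
#' Charge assigned to a tryptic peptide of a given length:
#' \code{clip(round(length / 7), 1, 5)}.
#'
#' @param length peptide length in residues.
#' @return Integer charge in 1..5.
#' @export
chargeModel <- function(length) {
    pmin(pmax(as.integer(round(length / 7)), 1L), 5L)
}

#' Simulate MS/MS spectra of a digested protein
#'
#' Digests the protein in silico and emits, for each product, a centroided
#' spectrum containing its complete singly charged b- and y-ion ladders with
#' Gaussian m/z jitter and log-normal intensities, plus uniformly
#' distributed decoy peaks in 50-1800 Th. Precursor m/z is the (modified)
#' monoisotopic value at the charge given by [chargeModel()].
#'
#' @param protein protein to digest.
#' @param mods fixed modifications (default carbamidomethyl-Cys).
#' @param maxMissed,minLength digestion parameters.
#' @param nDecoyPeaks decoy peaks added per spectrum.
#' @param mzJitterSD Gaussian m/z jitter SD (Th) on every ladder peak.
#' @param seed RNG seed.
#' @return list with \code{spectra} (list of [Spectrum-class]) and
#'   \code{manifest} (data.frame: peptide, start, end, missed, charge,
#'   precursorMz).
#' @export
simulateSpectra <- function(protein, mods = list(modCAM()), maxMissed = 1,
                            minLength = 5, nDecoyPeaks = 0, mzJitterSD = 0,
                            seed = 1) {
    set.seed(seed)
    dig <- trypticDigest(protein, maxMissed = maxMissed,
                         minLength = minLength)
    spectra <- vector("list", nrow(dig))
    for (i in seq_len(nrow(dig))) {
        pep <- dig$sequence[i]
        z <- chargeModel(nchar(pep))
        ladder <- fragmentLadder(pep, series = c("b", "y"), charge = 1L,
                                 mods = mods)
        mz <- ladder$mz + stats::rnorm(nrow(ladder), 0, mzJitterSD)
        int <- stats::rlnorm(nrow(ladder), meanlog = log(1000), sdlog = 0.5)
        if (nDecoyPeaks > 0) {
            mz <- c(mz, stats::runif(nDecoyPeaks, 50, 1800))
            int <- c(int, stats::rlnorm(nDecoyPeaks, log(300), 0.5))
        }
        spectra[[i]] <- Spectrum(mz, int,
            precursorMz = ionMz(peptideMonoMass(pep, mods), z),
            precursorCharge = z,
            id = sprintf("scan=%d pep=%s", i, pep))
    }
    dig$charge <- chargeModel(nchar(dig$sequence))
    dig$precursorMz <- vapply(seq_len(nrow(dig)), function(i)
        ionMz(peptideMonoMass(dig$sequence[i], mods), dig$charge[i]),
        numeric(1))
    list(spectra = spectra, manifest = dig)
}

#' Simulate a tight-binding inhibition assay
#'
#' Rates are \code{v0 * morrisonFraction(E, I, ki * (1 + S/Km)) * (1 + eps)}
#' with multiplicative Gaussian noise \code{eps ~ N(0, cv)}. Replicates are
#' averaged into a single rate per concentration.
#'
#' @param ki true inhibition constant (nM).
#' @param E enzyme concentration (nM).
#' @param S substrate concentration (uM).
#' @param Km substrate Km (uM).
#' @param I inhibitor concentration grid (nM).
#' @param cv multiplicative noise coefficient of variation (0 = noiseless).
#' @param v0 uninhibited rate.
#' @param replicates technical replicates averaged per concentration.
#' @param seed RNG seed.
#' @return An [InhibitionAssay-class].
#' @export
simulateInhibitionAssay <- function(ki, E, S, Km, I, cv = 0.05, v0 = 1,
                                    replicates = 1L, seed = 1) {
    set.seed(seed)
    kiApp <- ki * (1 + S / Km)
    truth <- v0 * morrisonFraction(E, I, kiApp)
    rate <- vapply(truth, function(mu)
        mean(mu * (1 + stats::rnorm(replicates, 0, cv))), numeric(1))
    InhibitionAssay(I, rate, v0 = v0, enzymeNM = E, substrateUM = S,
                    kmUM = Km, replicates = replicates)
}

#' Build a reference structure for trajectory simulation
#'
#' A coarse backbone (N, CA, C, O per residue) laid out along x, one or two
#' chains offset in y. Geometry is schematic; it exists to carry residue
#' metadata and interatomic distances for RMSF/H-bond/contact statistics.
#'
#' @param sequences named character vector: chain id -> one-letter sequence.
#' @param chainOffset y-offset between successive chains (A).
#' @return A single-frame [Trajectory-class].
#' @export
simulateReferenceStructure <- function(sequences = c(A = "ACDEFGHIKL"),
                                       chainOffset = 20) {
    rows <- list(); xyz <- list()
    three <- names(.RES3TO1)
    for (ci in seq_along(sequences)) {
        chain <- names(sequences)[ci]
        res <- .residues(sequences[[ci]])
        for (i in seq_along(res)) {
            x0 <- i * 3.8
            y0 <- (ci - 1L) * chainOffset
            resname <- three[match(res[i], .RES3TO1)]
            at <- data.frame(
                name = c("N", "CA", "C", "O"),
                element = c("N", "C", "C", "O"),
                resno = i, resname = resname, chain = chain,
                stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- at
            xyz[[length(xyz) + 1L]] <- rbind(
                c(x0 - 1.2, y0 + 0.8, 0), c(x0, y0, 0),
                c(x0 + 1.2, y0 + 0.8, 0), c(x0 + 1.3, y0 + 2.0, 0))
        }
    }
    atoms <- do.call(rbind, rows)
    coords <- do.call(rbind, xyz)
    Trajectory(array(coords, dim = c(1L, nrow(coords), 3L),
                     dimnames = NULL) * 1, atoms)
}

# uniform random rotation matrix (quaternion method)
.randomRotation <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
}

#' Simulate a Gaussian-fluctuation trajectory
#'
#' Frames are the reference coordinates plus independent Gaussian
#' displacements with a per-residue, per-axis amplitude (so the expected
#' C-alpha RMSF of residue r approaches \code{amplitude[r] * sqrt(3)}).
#' Optionally a random global rigid motion is applied per frame (to exercise
#' superposition), and a scripted donor/acceptor pair can be held at
#' hydrogen-bonding distance in an exact fraction of frames.
#'
#' @param reference single-frame [Trajectory-class] (e.g. from
#'   [simulateReferenceStructure()]).
#' @param amplitudes per-residue displacement SD (A), recycled across the
#'   reference's residues.
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @param rigidMotion apply a random global rotation+translation per frame.
#' @param hbond optional list \code{list(donor =, acceptor =, occupancy =)}
#'   of two atom indices scripted to sit at 2.9 A in exactly
#'   \code{round(occupancy * nFrames)} frames and 6.0 A otherwise.
#' @return A [Trajectory-class].
#' @export
simulateTrajectory <- function(reference, amplitudes = 0.5, nFrames = 1000,
                               seed = 1, rigidMotion = FALSE, hbond = NULL) {
    set.seed(seed)
    stopifnot(all(amplitudes >= 0))
    a <- reference@atoms
    resKey <- paste(a$chain, a$resno)
    resIds <- unique(resKey)
    amp <- rep_len(amplitudes, length(resIds))
    atomSd <- amp[match(resKey, resIds)]
    ref <- reference@coords[1, , , drop = TRUE]
    nA <- nrow(ref)
    coords <- array(NA_real_, dim = c(nFrames, nA, 3L))
    hbFrames <- logical(nFrames)
    if (!is.null(hbond)) {
        nOn <- round(hbond$occupancy * nFrames)
        hbFrames[sample.int(nFrames, nOn)] <- TRUE
    }
    for (f in seq_len(nFrames)) {
        fr <- ref + matrix(stats::rnorm(nA * 3L, 0, atomSd), nA, 3L)
        if (!is.null(hbond)) {
            d <- hbond$donor; ac <- hbond$acceptor
            gap <- if (hbFrames[f]) 2.9 else 6.0
            fr[ac, ] <- fr[d, ] + c(gap, 0, 0)
        }
        if (rigidMotion)
            fr <- sweep(fr %*% .randomRotation(), 2,
                        stats::rnorm(3, 0, 10), "+")
        coords[f, , ] <- fr
    }
    Trajectory(coords, a, reference@frameTimeNs)
}

#' Simulate a Kunitz-like multiple alignment
#'
#' Columns are drawn from three regimes: strictly identical (score 11),
#' mixed (a few distinct residues, intermediate scores), and gapped
#' (score 0), so the conservation profile spans the full score range.
#'
#' @param nSeqs number of sequences.
#' @param nColumns alignment length.
#' @param pIdentical probability a column is strictly identical.
#' @param pGap probability a column contains a gap.
#' @param seed RNG seed.
#' @return Named character vector of aligned sequences.
#' @export
simulateAlignment <- function(nSeqs = 14, nColumns = 52, pIdentical = 0.3,
                              pGap = 0.05, seed = 1) {
    set.seed(seed)
    res <- names(.AA_MONO)
    cols <- matrix("", nrow = nSeqs, ncol = nColumns)
    for (j in seq_len(nColumns)) {
        u <- stats::runif(1)
        if (u < pIdentical) {
            cols[, j] <- sample(res, 1L)
        } else if (u < pIdentical + pGap) {
            cols[, j] <- sample(res, nSeqs, replace = TRUE)
            cols[sample.int(nSeqs, 1L), j] <- "-"
        } else {
            pool <- sample(res, sample(2:5, 1L))
            cols[, j] <- sample(pool, nSeqs, replace = TRUE)
        }
    }
    aln <- apply(cols, 1, paste, collapse = "")
    names(aln) <- sprintf("AT%02d", seq_len(nSeqs))
    aln
}

#' Simulate conservation-correlated alanine-scan ddG tables
#'
#' For every homolog and every ungapped position, draws
#' \code{ddg = intercept + slope * columnScore + noise}. When
#' \code{targetR} is given, the noise SD is solved analytically from the
#' realized score variance so that the per-column mean ddG has the requested
#' expected Pearson correlation with the conservation score: the per-column
#' mean residual SD is \code{|slope| * sd(score) * sqrt(1/r^2 - 1)}, and
#' each homolog draw at a column observed by n homologs uses that SD times
#' \code{sqrt(n)}.
#'
#' @param aln named character vector of aligned sequences.
#' @param slope kcal/mol per score unit.
#' @param intercept kcal/mol.
#' @param noiseSD per-homolog noise SD (ignored when \code{targetR} given).
#' @param targetR desired expected Pearson r of score vs per-column mean ddG.
#' @param clamp optional \code{c(lo, hi)} band the ddG values are clipped to.
#' @param seed RNG seed.
#' @param table property table for scoring.
#' @return list with \code{ddg} (data.frame: homolog, position, wt, ddg),
#'   \code{profile} (the [ConservationProfile-class] used), and
#'   \code{noiseSD} actually applied (per-column-mean scale).
#' @export
simulateDdgTables <- function(aln, slope = 0.35, intercept = 0.3,
                              noiseSD = 0.5, targetR = NULL, clamp = NULL,
                              seed = 1, table = kunitzPropertyTable()) {
    set.seed(seed)
    profile <- scoreAlignment(aln, table)
    scores <- profile@scores
    mat <- do.call(rbind, strsplit(unname(aln), ""))
    nObs <- colSums(mat != "-")
    meanSD <- if (!is.null(targetR)) {
        abs(slope) * stats::sd(scores) * sqrt(1 / targetR^2 - 1)
    } else noiseSD
    rows <- list()
    for (i in seq_along(aln)) {
        cols <- which(mat[i, ] != "-")
        n <- nObs[cols]
        noise <- stats::rnorm(length(cols), 0, meanSD * sqrt(n))
        val <- intercept + slope * scores[cols] + noise
        if (!is.null(clamp)) val <- pmin(pmax(val, clamp[1]), clamp[2])
        rows[[i]] <- data.frame(homolog = names(aln)[i],
                                position = seq_along(cols),
                                wt = mat[i, cols], ddg = val,
                                stringsAsFactors = FALSE)
    }
    list(ddg = do.call(rbind, rows), profile = profile, noiseSD = meanSD)
}
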