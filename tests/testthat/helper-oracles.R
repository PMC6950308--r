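# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive second implementation, kept free of the package's code
# paths it verifies.

AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")

randomPeptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

# brute-force tryptic digest: enumerate every pair of cut sites (including
# the termini) and keep fragments whose internal cut-site count is within
# the missed-cleavage budget
oracleDigest <- function(seq, maxMissed, minLength = 1) {
    r <- strsplit(seq, "")[[1]]
    n <- length(r)
    sites <- which(r %in% c("K", "R") & c(r[-1], "") != "P")
    sites <- sites[sites < n]
    cuts <- c(0, sites, n)
    out <- list()
    for (a in seq_along(cuts)) for (b in seq_along(cuts)) {
        if (cuts[b] <= cuts[a]) next
        internal <- sum(sites > cuts[a] & sites < cuts[b])
        if (internal > maxMissed) next
        if (cuts[b] - cuts[a] < minLength) next
        out[[length(out) + 1L]] <- data.frame(
            sequence = substr(seq, cuts[a] + 1, cuts[b]),
            start = cuts[a] + 1L, end = cuts[b], missed = internal)
    }
    d <- do.call(rbind, out)
    d[order(d$start, d$end), ]
}

# exhaustive peak assignment: all (ion, peak) pairs within tol, assigned
# best-error-first; mirrors the matching contract independently
oracleAnnotate <- function(theo, obsMz, tol) {
    pairs <- expand.grid(ion = seq_along(theo), peak = seq_along(obsMz))
    pairs$err <- abs(theo[pairs$ion] - obsMz[pairs$peak])
    pairs <- pairs[pairs$err <= tol, ]
    pairs <- pairs[order(pairs$err), ]
    usedI <- logical(length(theo)); usedP <- logical(length(obsMz))
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        if (!usedI[pairs$ion[i]] && !usedP[pairs$peak[i]]) {
            keep[i] <- TRUE
            usedI[pairs$ion[i]] <- TRUE; usedP[pairs$peak[i]] <- TRUE
        }
    }
    pairs[keep, ]
}

# codon-dictionary translation oracle (independent of Biostrings)
GENETIC_CODE_TAB <- local({
    bases <- c("T", "C", "A", "G")
    aas <- strsplit(paste0(
        "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
    codons <- as.vector(t(outer(bases, as.vector(t(outer(bases, bases,
        paste0))), paste0)))
    stats::setNames(aas, codons)
})

oracleTranslate <- function(nt, offset = 0) {
    nt <- toupper(nt)
    n <- (nchar(nt) - offset) %/% 3
    if (n < 1) return("")
    codons <- substring(nt, offset + 1 + 3 * (seq_len(n) - 1),
                        offset + 3 * seq_len(n))
    aa <- GENETIC_CODE_TAB[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

oracleRevComp <- function(nt) {
    map <- c(A = "T", T = "A", G = "C", C = "G", N = "N")
    paste(rev(map[strsplit(toupper(nt), "")[[1]]]), collapse = "")
}

# brute-force tag scan: slide the class list over every position of every
# protein, both readings
oracleTagScan <- function(proteins, classes) {
    hits <- list()
    for (orient in c("forward", "reverse")) {
        cc <- if (orient == "forward") classes else rev(classes)
        L <- length(cc)
        for (p in names(proteins)) {
            r <- strsplit(proteins[[p]], "")[[1]]
            if (length(r) < L) next
            for (s in seq_len(length(r) - L + 1)) {
                if (all(mapply(function(res, cl) res %in% cl,
                               r[s:(s + L - 1)], cc)))
                    hits[[length(hits) + 1L]] <- data.frame(
                        proteinId = p, offset = s, orientation = orient)
            }
        }
        if (identical(cc, rev(cc))) break
    }
    if (!length(hits)) return(data.frame(proteinId = character(),
                                         offset = integer(),
                                         orientation = character()))
    do.call(rbind, hits)
}

# quaternion (Horn) absolute-orientation oracle for superposition RMSD
oracleSuperposeRMSD <- function(mobile, ref) {
    mc <- scale(mobile, scale = FALSE)
    rc <- scale(ref, scale = FALSE)
    M <- t(mc) %*% rc
    Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
    Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
    Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
    N <- matrix(c(
        Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
        Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
        Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
        Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4,
        byrow = TRUE)
    lambda <- max(eigen(N, symmetric = TRUE)$values)
    e2 <- sum(mc^2) + sum(rc^2) - 2 * lambda
    sqrt(max(e2, 0) / nrow(mobile))
}

# naive per-frame double loop for interaction occupancies
oraclePairOccupancy <- function(traj, i, j, cutoff) {
    nF <- nFrames(traj)
    hit <- 0L
    for (f in seq_len(nF)) {
        x <- frameCoords(traj, f)
        if (sqrt(sum((x[i, ] - x[j, ])^2)) <= cutoff) hit <- hit + 1L
    }
    hit / nF
}

# property-count conservation oracle: literal reading of the scoring rule
oracleAmas <- function(column, table) {
    if (any(column == "-")) return(0L)
    if (length(unique(column)) == 1L) return(11L)
    cnt <- 0L
    for (p in names(table)) {
        inside <- column %in% table[[p]]
        if (all(inside) || all(!inside)) cnt <- cnt + 1L
    }
    min(cnt, 10L)
}
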