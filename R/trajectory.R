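#' Construct a trajectory
#'
#' @param coords numeric array frames x atoms x 3 (Angstrom); a single
#'   atoms x 3 matrix is promoted to one frame.
#' @param atoms data.frame with columns \code{name, element, resno, resname,
#'   chain}.
#' @param frameTimeNs time per frame in ns (optional).
#' @return A [Trajectory-class].
#' @export
Trajectory <- function(coords, atoms, frameTimeNs = NA_real_) {
    if (length(dim(coords)) == 2L)
        coords <- array(coords, dim = c(1L, dim(coords)))
    new("Trajectory", coords = coords, atoms = atoms,
        frameTimeNs = as.numeric(frameTimeNs))
}

#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

#' @rdname accessors
#' @export
setMethod("atomTable", "Trajectory", function(x) x@atoms)

#' @rdname accessors
#' @param frame frame index.
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame)
    x@coords[frame, , , drop = TRUE])

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d frames x %d atoms (%d residues, chains %s)\n",
                dim(object@coords)[1], dim(object@coords)[2],
                length(unique(paste(object@atoms$chain, object@atoms$resno))),
                paste(unique(object@atoms$chain), collapse = ",")))
})

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks of a PDB file (via bio3d) into a
#' [Trajectory-class].
#'
#' @param path PDB file path.
#' @param frameTimeNs time per frame in ns (optional metadata).
#' @return A [Trajectory-class].
#' @export
readTrajectoryPDB <- function(path, frameTimeNs = NA_real_) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nA <- ncol(xyz) %/% 3L
    coords <- array(NA_real_, dim = c(nrow(xyz), nA, 3L))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3L, length.out = nA),
                                        drop = FALSE]
    atoms <- data.frame(name = pdb$atom$elety,
                        element = sub("^([A-Za-z]).*", "\\1", pdb$atom$elety),
                        resno = pdb$atom$resno, resname = pdb$atom$resid,
                        chain = ifelse(is.na(pdb$atom$chain), "A",
                                       pdb$atom$chain),
                        stringsAsFactors = FALSE)
    Trajectory(coords, atoms, frameTimeNs)
}

#' Write a trajectory (or average structure) as PDB
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @param average write the frame-averaged structure as a single model
#'   instead of all frames.
#' @return The path, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path, average = FALSE) {
    a <- traj@atoms
    frames <- if (average) 1L else seq_len(nFrames(traj))
    con <- file(path, "w")
    on.exit(close(con))
    for (f in frames) {
        xyz <- if (average) apply(traj@coords, c(2, 3), mean)
               else traj@coords[f, , , drop = TRUE]
        writeLines(sprintf("MODEL     %4d", f), con)
        writeLines(sprintf(
            "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(nrow(a)), a$name, a$resname, a$chain, a$resno,
            xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

# Kabsch least-squares rotation R minimizing ||x R - y|| (row vectors,
# both inputs centered n x 3)
.kabsch <- function(x, y) {
    s <- svd(crossprod(x, y))
    d <- sign(det(s$u %*% t(s$v)))
    s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.resolveSelection <- function(traj, selection) {
    if (is.character(selection) && length(selection) <= 4)
        which(traj@atoms$name %in% selection)
    else if (is.logical(selection)) which(selection)
    else as.integer(selection)
}

#' Superpose trajectory frames onto a reference
#'
#' Least-squares rigid-body (Kabsch) superposition of every frame's selected
#' atoms onto the reference frame. The transform fitted on the selection is
#' applied to all atoms.
#'
#' @param traj a [Trajectory-class].
#' @param reference reference frame index.
#' @param selection atom-name character vector (e.g. \code{"CA"}), logical
#'   mask, or integer atom indices; >= 3 atoms required.
#' @return Aligned [Trajectory-class] with per-frame selection RMSD (in
#'   Angstrom) in attribute \code{"rmsd"}.
#' @export
superposeFrames <- function(traj, reference = 1L, selection = "CA") {
    sel <- .resolveSelection(traj, selection)
    if (length(sel) < 3L)
        stop("superposition needs >= 3 selected atoms", call. = FALSE)
    ref <- traj@coords[reference, sel, , drop = TRUE]
    refC <- colMeans(ref)
    refCtr <- sweep(ref, 2, refC)
    out <- traj@coords
    rmsd <- numeric(nFrames(traj))
    for (f in seq_len(nFrames(traj))) {
        mob <- traj@coords[f, sel, , drop = TRUE]
        mobC <- colMeans(mob)
        R <- .kabsch(sweep(mob, 2, mobC), refCtr)
        all <- sweep(traj@coords[f, , , drop = TRUE], 2, mobC)
        out[f, , ] <- sweep(all %*% R, 2, refC, "+")
        d <- out[f, sel, , drop = TRUE] - ref
        rmsd[f] <- sqrt(mean(rowSums(d^2)))
    }
    res <- Trajectory(out, traj@atoms, traj@frameTimeNs)
    attr(res, "rmsd") <- rmsd
    res
}

#' Per-residue root-mean-square fluctuation
#'
#' For each selected atom, the square root of the time-mean squared
#' deviation from its time-mean position, aggregated per residue (mean over
#' the residue's selected atoms). Frames should be superposed first.
#'
#' @param traj an aligned [Trajectory-class].
#' @param selection atom selection (default C-alpha).
#' @param window integer frame indices to use (default all frames).
#' @return data.frame with columns \code{chain, resno, resname, rmsf} (A).
#' @export
rmsf <- function(traj, selection = "CA", window = NULL) {
    sel <- .resolveSelection(traj, selection)
    if (!length(sel)) stop("empty selection", call. = FALSE)
    if (is.null(window)) window <- seq_len(nFrames(traj))
    if (!length(window)) stop("empty frame window", call. = FALSE)
    stopifnot(all(window >= 1 & window <= nFrames(traj)))
    x <- traj@coords[window, sel, , drop = FALSE]
    mean_ <- apply(x, c(2, 3), mean)
    dev2 <- sweep(x, c(2, 3), mean_)^2
    atomRmsf <- sqrt(apply(dev2, 2, sum) / length(window))
    a <- traj@atoms[sel, , drop = FALSE]
    key <- paste(a$chain, a$resno)
    agg <- tapply(atomRmsf, key, mean)
    first <- !duplicated(key)
    ord <- order(a$chain[first], a$resno[first])
    data.frame(chain = a$chain[first], resno = a$resno[first],
               resname = a$resname[first],
               rmsf = as.numeric(agg[key[first]]))[ord, ] |>
        (\(d) { rownames(d) <- NULL; d })()
}

# donor / acceptor heavy atoms of the standard residues
.HB_DONORS <- list(backbone = "N",
    S = "OG", T = "OG1", Y = "OH", N = "ND2", Q = "NE2", K = "NZ",
    R = c("NE", "NH1", "NH2"), H = c("ND1", "NE2"), W = "NE1")
.HB_ACCEPTORS <- list(backbone = "O",
    D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
    S = "OG", T = "OG1", Y = "OH", H = c("ND1", "NE2"))

.RES3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.hbRole <- function(atoms, dict) {
    one <- .RES3TO1[atoms$resname]
    one[is.na(one)] <- atoms$resname[is.na(one)]   # allow 1-letter input
    hit <- atoms$name %in% dict$backbone
    for (res in setdiff(names(dict), "backbone"))
        hit <- hit | (one == res & atoms$name %in% dict[[res]])
    # proline backbone N has no hydrogen
    if (identical(dict$backbone, "N")) hit <- hit & !(one == "P" &
                                                     atoms$name == "N")
    which(hit)
}

.pairDist <- function(coords, i, j) {
    # distance between atoms i and j across frames
    d <- coords[, i, , drop = FALSE] - coords[, j, , drop = FALSE]
    sqrt(rowSums(matrix(d, nrow = dim(coords)[1])^2))
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A donor-acceptor pair is hydrogen-bonded in a frame when the heavy-atom
#' distance is at most \code{dCut}; when hydrogens are present, the
#' donor-H-acceptor angle must also be at least \code{aCut} (the hydrogen is
#' assigned to its donor by covalent distance < 1.2 A in the first frame).
#' Without hydrogens the criterion is distance-only. Occupancy is the
#' fraction of frames the bond exists; classes follow the 30\%/85\%
#' reporting thresholds (\code{">=85\%"} strong, \code{">=30\%"} reported).
#'
#' @param traj a [Trajectory-class].
#' @param dCut donor-acceptor distance cutoff (A).
#' @param aCut donor-H-acceptor angle cutoff (degrees); used only when
#'   hydrogens are present.
#' @param intermolecular restrict to donor/acceptor on different chains.
#' @param minOccupancy report only pairs at or above this occupancy.
#' @return data.frame with columns \code{donor, acceptor, occupancy, class}
#'   plus the criteria echoed as attributes \code{dCut}, \code{aCut},
#'   \code{angleUsed}.
#' @export
hbondOccupancy <- function(traj, dCut = 3.5, aCut = 150,
                           intermolecular = TRUE, minOccupancy = 0) {
    a <- traj@atoms
    don <- .hbRole(a, .HB_DONORS)
    acc <- .hbRole(a, .HB_ACCEPTORS)
    out <- data.frame(donor = character(), acceptor = character(),
                      occupancy = numeric(), class = character())
    if (!length(don) || !length(acc)) {
        warning("no donors/acceptors found")
        attr(out, "dCut") <- dCut; attr(out, "aCut") <- aCut
        attr(out, "angleUsed") <- FALSE
        return(out)
    }
    hyd <- which(a$element == "H")
    useAngle <- length(hyd) > 0
    donH <- NULL
    if (useAngle) {
        f1 <- traj@coords[1, , , drop = TRUE]
        donH <- lapply(don, function(d) {
            dd <- sqrt(colSums((t(f1[hyd, , drop = FALSE]) - f1[d, ])^2))
            hyd[dd < 1.2]
        })
    }
    lbl <- function(i) sprintf("%s%d-%s%s", a$chain[i], a$resno[i],
                               .RES3TO1[a$resname[i]] %||% a$resname[i],
                               a$name[i])
    rows <- list()
    nF <- nFrames(traj)
    for (di in seq_along(don)) {
        d <- don[di]
        for (ac in acc) {
            if (ac == d) next
            if (a$resno[ac] == a$resno[d] && a$chain[ac] == a$chain[d]) next
            if (intermolecular && a$chain[ac] == a$chain[d]) next
            ok <- .pairDist(traj@coords, d, ac) <= dCut
            if (useAngle && length(donH[[di]]) && any(ok)) {
                angOk <- rep(FALSE, nF)
                for (h in donH[[di]]) {
                    v1 <- traj@coords[, d, , drop = TRUE] -
                          traj@coords[, h, , drop = TRUE]
                    v2 <- traj@coords[, ac, , drop = TRUE] -
                          traj@coords[, h, , drop = TRUE]
                    if (nF == 1L) { v1 <- rbind(v1); v2 <- rbind(v2) }
                    cosA <- rowSums(v1 * v2) /
                        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
                    angOk <- angOk | (acos(pmin(pmax(cosA, -1), 1)) * 180 /
                                      pi >= aCut)
                }
                ok <- ok & angOk
            }
            occ <- sum(ok) / nF
            if (occ > 0 && occ >= minOccupancy)
                rows[[length(rows) + 1L]] <- data.frame(
                    donor = lbl(d), acceptor = lbl(ac), occupancy = occ,
                    stringsAsFactors = FALSE)
        }
    }
    if (length(rows)) {
        out <- do.call(rbind, rows)
        out$class <- cut(out$occupancy, c(-Inf, 0.30, 0.85, Inf),
                         labels = c("weak", "reported", "strong"),
                         right = FALSE)
        # occupancy exactly 0.85 is strong per the >=85% threshold
        out <- out[order(-out$occupancy), , drop = FALSE]
        rownames(out) <- NULL
    }
    attr(out, "dCut") <- dCut
    attr(out, "aCut") <- aCut
    attr(out, "angleUsed") <- useAngle
    out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Close-contact occupancy per residue pair
#'
#' A residue pair is in contact in a frame when any interatomic distance is
#' below \code{cutoff}. Occupancy is the fraction of frames in contact.
#'
#' @param traj a [Trajectory-class].
#' @param cutoff distance cutoff (A), default 4.
#' @param intermolecular restrict to residue pairs on different chains
#'   (requires >= 2 chains).
#' @return data.frame with columns \code{chainA, resnoA, chainB, resnoB,
#'   occupancy}, ordered by decreasing occupancy.
#' @export
closeContacts <- function(traj, cutoff = 4.0, intermolecular = TRUE) {
    a <- traj@atoms
    chains <- unique(a$chain)
    if (intermolecular && length(chains) < 2)
        stop("intermolecular mode requires >= 2 chains", call. = FALSE)
    res <- unique(data.frame(chain = a$chain, resno = a$resno))
    res <- res[order(res$chain, res$resno), , drop = FALSE]
    atomsOf <- lapply(seq_len(nrow(res)), function(i)
        which(a$chain == res$chain[i] & a$resno == res$resno[i]))
    nF <- nFrames(traj)
    rows <- list()
    for (i in seq_len(nrow(res) - 1L)) {
        for (j in (i + 1L):nrow(res)) {
            if (intermolecular && res$chain[i] == res$chain[j]) next
            ai <- atomsOf[[i]]; aj <- atomsOf[[j]]
            inContact <- rep(FALSE, nF)
            for (p in ai) for (q in aj)
                inContact <- inContact | (.pairDist(traj@coords, p, q) <
                                          cutoff)
            occ <- sum(inContact) / nF
            if (occ > 0)
                rows[[length(rows) + 1L]] <- data.frame(
                    chainA = res$chain[i], resnoA = res$resno[i],
                    chainB = res$chain[j], resnoB = res$resno[j],
                    occupancy = occ, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(chainA = character(), resnoA = integer(),
                          chainB = character(), resnoB = integer(),
                          occupancy = numeric()))
    out <- do.call(rbind, rows)
    out <- out[order(-out$occupancy), , drop = FALSE]
    rownames(out) <- NULL
    out
}
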