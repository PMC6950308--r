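#' @rdname accessors
#' @export
setMethod("tagClasses", "SequenceTag", function(x) x@classes)

#' @rdname accessors
#' @export
setMethod("tagDirection", "SequenceTag", function(x) x@direction)

setMethod("show", "SequenceTag", function(object) {
    cat(sprintf("SequenceTag %s (%s-ladder, %.3f-%.3f Th)\n",
                tagString(object), object@direction, object@anchorMzLow,
                object@anchorMzHigh))
})

#' Compact string form of a tag
#'
#' Single residues printed plainly, ambiguity classes bracketed,
#' e.g. \code{"N[IL]PAV"}.
#'
#' @param tag a [SequenceTag-class].
#' @return character string.
#' @export
tagString <- function(tag) {
    paste(vapply(tag@classes, function(cl)
        if (length(cl) == 1L) cl else
            paste0("[", paste(sort(cl), collapse = ""), "]"), ""),
        collapse = "")
}

# residue masses admissible as peak spacings: base residues plus each fixed
# modification applied to its targets (e.g. CAM-Cys at 160.03065)
.gapMasses <- function(mods) {
    masses <- .AA_MONO
    labels <- names(.AA_MONO)
    for (m in mods) {
        masses <- c(masses, .AA_MONO[m@targets] + m@deltaMono)
        labels <- c(labels, m@targets)
    }
    list(mass = unname(masses), residue = labels)
}

#' Deduce sequence tags from product-ion spacings
#'
#' Builds a directed gap graph over the peaks of a spectrum: an edge connects
#' peaks i -> j (ascending m/z) when the spacing matches a residue mass
#' (fixed modifications included) within \code{tol}. All maximal paths of at
#' least \code{minTagLen} edges are emitted as sequence tags; each path
#' position carries the ambiguity class of all residues compatible with that
#' spacing (I/L always coincide; K/Q merge once \code{tol} covers their
#' 0.03638 Da difference).
#'
#' Stored tag classes read in ascending-m/z order, which is N-to-C for a
#' b-series ladder and C-to-N for a y-series ladder; [searchTags()] therefore
#' scans both orientations.
#'
#' @param spectrum a [Spectrum-class].
#' @param tol spacing tolerance (Th).
#' @param minTagLen minimum tag length in residues.
#' @param mods fixed modifications admissible as spacings.
#' @param maxPaths cap on enumerated paths per spectrum (combinatorial guard).
#' @return list of [SequenceTag-class] objects.
#' @export
deduceTags <- function(spectrum, tol = 0.3, minTagLen = 4, mods = list(),
                       maxPaths = 200) {
    stopifnot(is(spectrum, "Spectrum"), tol > 0)
    mz <- spectrum@mz
    n <- length(mz)
    if (n < 2L) return(list())
    gm <- .gapMasses(mods)
    edges <- vector("list", n)     # per-node outgoing edges
    hasIn <- logical(n)
    maxGap <- max(gm$mass) + tol
    for (i in seq_len(n - 1L)) {
        js <- which(mz > mz[i] & mz <= mz[i] + maxGap)
        ee <- list()
        for (j in js) {
            cl <- unique(gm$residue[abs(mz[j] - mz[i] - gm$mass) <= tol])
            if (length(cl)) {
                ee[[length(ee) + 1L]] <- list(to = j, class = sort(cl))
                hasIn[j] <- TRUE
            }
        }
        edges[[i]] <- ee
    }
    hasOut <- vapply(edges, function(e) length(e) > 0L, TRUE)
    paths <- list()
    # depth-first enumeration of maximal paths from source nodes
    walk <- function(node, classes, startMz) {
        if (length(paths) >= maxPaths) return()
        ee <- edges[[node]]
        if (!length(ee)) {
            if (length(classes) >= minTagLen)
                paths[[length(paths) + 1L]] <<- new("SequenceTag",
                    classes = classes, anchorMzLow = startMz,
                    anchorMzHigh = mz[node], direction = "b")
            return()
        }
        for (e in ee)
            walk(e$to, c(classes, list(e$class)), startMz)
    }
    for (s in which(!hasIn & hasOut)) walk(s, list(), mz[s])
    paths
}

#' Search sequence tags against protein sequences
#'
#' Reports every position where the tag's residue classes match a substring
#' of a protein. Both readings of each tag are scanned (the stored order and
#' its reverse), since a y-ladder tag reads C-to-N.
#'
#' @param proteins named character vector of protein sequences.
#' @param tags list of [SequenceTag-class] objects.
#' @return data.frame with columns \code{proteinId, offset, tag, orientation,
#'   length} (1-based offsets; orientation \code{"forward"} or
#'   \code{"reverse"}).
#' @examples
#' tag <- new("SequenceTag", classes = list("G", "G"), anchorMzLow = 0,
#'            anchorMzHigh = 0, direction = "b")
#' searchTags(c(p1 = "AGGA"), list(tag))
#' @export
searchTags <- function(proteins, tags) {
    if (is.null(names(proteins)))
        names(proteins) <- paste0("protein", seq_along(proteins))
    # one subject string with '#' separators: a single regex scan per
    # tag/orientation instead of one per protein
    subject <- paste(proteins, collapse = "#")
    bounds <- c(0L, cumsum(nchar(proteins) + 1L))
    out <- list()
    for (t in seq_along(tags)) {
        cls <- tags[[t]]@classes
        for (orient in c("forward", "reverse")) {
            cc <- if (orient == "forward") cls else rev(cls)
            pat <- paste0("(?=", paste(vapply(cc, function(x)
                if (length(x) == 1L) x else
                    paste0("[", paste(x, collapse = ""), "]"), ""),
                collapse = ""), ")")
            hit <- gregexpr(pat, subject, perl = TRUE)[[1]]
            if (hit[1] != -1L) {
                pos <- as.integer(hit)
                pi <- findInterval(pos - 1L, bounds)
                out[[length(out) + 1L]] <- data.frame(
                    proteinId = names(proteins)[pi],
                    offset = pos - bounds[pi], tag = t,
                    orientation = orient, length = length(cls),
                    stringsAsFactors = FALSE)
            }
            # palindromic tags would double-report identical hits
            if (identical(cc, rev(cc))) break
        }
    }
    if (!length(out))
        return(data.frame(proteinId = character(), offset = integer(),
                          tag = integer(), orientation = character(),
                          length = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
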