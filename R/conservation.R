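#' Physico-chemical property table for conservation scoring
#'
#' Taylor/Zvelebil-style residue property memberships used by the
#' column-wise conservation score: ten properties (hydrophobic, positive,
#' negative, polar, charged, small, tiny, aliphatic, aromatic, proline).
#' The table is an argument everywhere it is used, so alternative
#' classifications can be swapped in.
#'
#' @return Named list of 10 character vectors (property -> residues).
#' @examples
#' kunitzPropertyTable()$aliphatic
#' @export
kunitzPropertyTable <- function() {
    pos <- c("H", "K", "R"); neg <- c("D", "E")
    list(hydrophobic = c("A", "C", "F", "G", "H", "I", "K", "L", "M", "T",
                         "V", "W", "Y"),
         positive = pos, negative = neg, charged = c(pos, neg),
         polar = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "W",
                   "Y"),
         small = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
         tiny = c("A", "G", "S"),
         aliphatic = c("I", "L", "V"),
         aromatic = c("F", "H", "W", "Y"),
         proline = "P")
}

#' Conservation score of one alignment column
#'
#' A column of identical residues with no gaps scores 11. Otherwise the
#' score is the number of the ten physico-chemical properties whose
#' membership indicator is uniform across all residues in the column
#' (all residues have it, or all lack it), capped at 10; a gap breaks every
#' property, so gapped columns score 0.
#'
#' @param column character vector of residues (gaps as \code{"-"}).
#' @param table property table, see [kunitzPropertyTable()].
#' @return Integer score in 0..11.
#' @examples
#' amasScoreColumn(c("K", "K", "K"))        # 11
#' amasScoreColumn(c("I", "L", "V"))        # uniform properties counted
#' amasScoreColumn(c("K", "-", "K"))        # 0
#' @export
amasScoreColumn <- function(column, table = kunitzPropertyTable()) {
    stopifnot(length(column) >= 1)
    bad <- setdiff(column, c(names(.AA_MONO), "-"))
    if (length(bad))
        stop(sprintf("unknown residue code(s): %s",
                     paste(unique(bad), collapse = ", ")), call. = FALSE)
    if (any(column == "-")) return(0L)
    if (length(unique(column)) == 1L) return(11L)
    uniform <- vapply(table, function(members) {
        has <- column %in% members
        all(has) || !any(has)
    }, TRUE)
    min(sum(uniform), 10L)
}

#' Score a multiple alignment column-by-column
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gaps as \code{"-"}), or a \code{Biostrings::AAMultipleAlignment} /
#'   \code{AAStringSet}.
#' @param table property table.
#' @return A [ConservationProfile-class].
#' @examples
#' p <- scoreAlignment(c(a = "KCV-", b = "KCI-"))
#' conservationScores(p)
#' @export
scoreAlignment <- function(aln, table = kunitzPropertyTable()) {
    if (is(aln, "AAMultipleAlignment"))
        aln <- as.character(Biostrings::unmasked(aln))
    if (is(aln, "AAStringSet")) aln <- as.character(aln)
    stopifnot(length(aln) >= 2, length(unique(nchar(aln))) == 1)
    mat <- do.call(rbind, strsplit(aln, ""))
    cols <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
    new("ConservationProfile",
        scores = vapply(cols, amasScoreColumn, 0L, table = table),
        columns = cols)
}

#' @rdname accessors
#' @export
setMethod("conservationScores", "ConservationProfile", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("scoreHistogram", "ConservationProfile", function(x)
    table(factor(x@scores, levels = 0:11)))

setMethod("show", "ConservationProfile", function(object) {
    cat(sprintf("ConservationProfile: %d columns, scores %s\n",
                length(object@scores),
                paste(range(object@scores), collapse = "-")))
})

#' Bin conservation scores into reporting groups
#'
#' Assigns each column to exactly one score bin. The default bins follow the
#' conserved-to-variable reporting groups 9-11, 5-8, 2-4, 0-1.
#'
#' @param profile a [ConservationProfile-class] (or integer score vector).
#' @param bins list of \code{c(lo, hi)} inclusive ranges; must partition
#'   0..11 without overlap.
#' @return Factor of bin labels (\code{"lo-hi"}), one per column.
#' @export
binScores <- function(profile,
                      bins = list(c(9, 11), c(5, 8), c(2, 4), c(0, 1))) {
    scores <- if (is(profile, "ConservationProfile"))
        profile@scores else as.integer(profile)
    covered <- sort(unlist(lapply(bins, function(b) b[1]:b[2])))
    if (!identical(covered, 0:11))
        stop("bins must partition 0..11 without overlap", call. = FALSE)
    labels <- vapply(bins, function(b) paste(b, collapse = "-"), "")
    idx <- vapply(scores, function(s)
        which(vapply(bins, function(b) s >= b[1] && s <= b[2], TRUE)), 0L)
    factor(labels[idx], levels = labels)
}

#' Per-column mean ddG across homologs
#'
#' Maps each homolog's ungapped residue positions through the alignment to
#' columns, then averages the alanine-scan ddG values per column over the
#' homologs that have a value there. Columns with no observation are
#' reported as NA with count 0 (missing, not zero).
#'
#' @param ddg data.frame with columns \code{homolog, position, ddg}
#'   (1-based ungapped positions; Ala/Gly positions may be absent).
#' @param aln named character vector of aligned sequences; names must cover
#'   the homolog ids in \code{ddg}.
#' @return data.frame with columns \code{column, meanDdg, n}.
#' @export
meanDdgPerColumn <- function(ddg, aln) {
    stopifnot(all(ddg$homolog %in% names(aln)))
    width <- unique(nchar(aln))
    stopifnot(length(width) == 1)
    sums <- numeric(width); counts <- integer(width)
    for (h in unique(ddg$homolog)) {
        res <- strsplit(aln[[h]], "")[[1]]
        colOf <- which(res != "-")      # ungapped position -> column
        sub <- ddg[ddg$homolog == h, , drop = FALSE]
        if (any(sub$position > length(colOf)))
            stop(sprintf("position beyond sequence length for homolog %s", h),
                 call. = FALSE)
        cols <- colOf[sub$position]
        sums[cols] <- sums[cols] + sub$ddg
        counts[cols] <- counts[cols] + 1L
    }
    data.frame(column = seq_len(width),
               meanDdg = ifelse(counts > 0, sums / pmax(counts, 1L), NA),
               n = counts)
}

#' Conservation-vs-stability regression
#'
#' Ordinary least squares of per-column mean ddG on the conservation score,
#' with the Pearson correlation of the paired values. Columns missing either
#' value are dropped; zero variance in either variable yields \code{r = NA}
#' with a flag.
#'
#' @param profile a [ConservationProfile-class] or integer score vector.
#' @param meanDdg numeric vector of per-column mean ddG (kcal/mol), NA for
#'   missing columns (or the data.frame from [meanDdgPerColumn()]).
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{n},
#'   \code{degenerate} (TRUE when a variance was zero).
#' @export
conservationStabilityRegression <- function(profile, meanDdg) {
    scores <- if (is(profile, "ConservationProfile"))
        profile@scores else as.numeric(profile)
    if (is.data.frame(meanDdg)) meanDdg <- meanDdg$meanDdg
    ok <- !is.na(scores) & !is.na(meanDdg)
    if (sum(ok) < 3)
        stop("need >= 3 columns with both values", call. = FALSE)
    x <- scores[ok]; y <- meanDdg[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                    n = sum(ok), degenerate = TRUE))
    fit <- stats::lm(y ~ x)
    list(r = stats::cor(x, y), slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]), n = sum(ok),
         degenerate = FALSE)
}
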