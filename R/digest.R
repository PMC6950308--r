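#' In silico tryptic digestion
#'
#' Cleaves a protein C-terminal to K and R, except when the next residue is
#' proline, and enumerates all products with up to \code{maxMissed} internal
#' (missed) cleavage sites and at least \code{minLength} residues. Positions
#' are 1-based inclusive coordinates on the parent.
#'
#' @param seq protein sequence (one-letter codes).
#' @param maxMissed maximum number of missed cleavages per product.
#' @param minLength minimum product length.
#' @return A data.frame with columns \code{sequence, start, end, missed}.
#'   The zero-missed products partition the parent exactly.
#' @examples
#' trypticDigest("DANSFCQLPAVVGKCRGYFPR", maxMissed = 1)
#' trypticDigest("KPK")   # no cleavage before proline
#' @export
trypticDigest <- function(seq, maxMissed = 2, minLength = 1) {
    if (maxMissed < 0) stop("maxMissed must be >= 0", call. = FALSE)
    if (!nzchar(seq))
        return(data.frame(sequence = character(), start = integer(),
                          end = integer(), missed = integer()))
    r <- .residues(seq)
    n <- length(r)
    # cut after position i when r[i] in K/R and r[i+1] != P
    cuts <- which(r %in% c("K", "R") & c(r[-1], "") != "P")
    cuts <- cuts[cuts < n]
    bounds <- c(0L, cuts, n)            # fragment i spans bounds[i]+1..bounds[i+1]
    nb <- length(bounds) - 1L
    out <- vector("list", 0L)
    for (i in seq_len(nb)) {
        for (j in i:min(nb, i + maxMissed)) {
            s <- bounds[i] + 1L
            e <- bounds[j + 1L]
            if (e - s + 1L < minLength) next
            out[[length(out) + 1L]] <- data.frame(
                sequence = substr(seq, s, e), start = s, end = e,
                missed = j - i, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(sequence = character(), start = integer(),
                          end = integer(), missed = integer()))
    do.call(rbind, out)
}
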