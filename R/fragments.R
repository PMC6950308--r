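#' Theoretical fragment-ion m/z
#'
#' m/z of a CID product ion of a linear peptide. For a peptide of length n
#' with prefix residue-mass sums P(i) and suffix sums S(i) (fixed mods
#' included):
#' \itemize{
#'   \item b_i = (P(i) + z * 1.00728) / z
#'   \item y_i = (S(i) + water + z * 1.00728) / z
#'   \item a_i = b_i - CO/z (CO = 27.99491 Da)
#'   \item z_i = y_i - NH3/z + H/z (z-dot radical convention:
#'     y - 17.02655 + 1.00783 per charge)
#' }
#'
#' @param seq peptide sequence.
#' @param series one of \code{"a"}, \code{"b"}, \code{"y"}, \code{"z"}.
#' @param index fragment index, 1 <= index < nchar(seq).
#' @param charge fragment charge (>= 1).
#' @param mods fixed modifications.
#' @return m/z in Th.
#' @examples
#' fragmentMz("AG", "b", 1)                      # 72.0444
#' fragmentMz("PEPTIDEK", "y", 1)                # C-terminal K: 147.1128
#' @export
fragmentMz <- function(seq, series = c("b", "y", "a", "z"), index,
                       charge = 1L, mods = list()) {
    series <- match.arg(series)
    r <- .residues(seq)
    n <- length(r)
    if (any(index < 1L) || any(index >= n))
        stop("fragment index must satisfy 1 <= index < peptide length",
             call. = FALSE)
    mass1 <- .AA_MONO[r]
    for (m in mods)
        mass1[r %in% m@targets] <- mass1[r %in% m@targets] + m@deltaMono
    pre <- cumsum(mass1)
    suf <- rev(cumsum(rev(mass1)))
    neutral <- unname(switch(series,
        b = pre[index],
        a = pre[index] - .CO_MONO,
        y = suf[n - index + 1L] + .WATER_MONO,
        z = suf[n - index + 1L] + .WATER_MONO - .NH3_MONO + 1.00783))
    (neutral + charge * .PROTON) / charge
}

#' Full theoretical fragment ladder
#'
#' All fragment ions of the requested series at the given charge, as a table.
#'
#' @inheritParams fragmentMz
#' @return data.frame with columns \code{series, index, charge, mz}.
#' @export
fragmentLadder <- function(seq, series = c("b", "y"), charge = 1L,
                           mods = list()) {
    n <- nchar(seq)
    do.call(rbind, lapply(series, function(s)
        data.frame(series = s, index = seq_len(n - 1L), charge = charge,
                   mz = vapply(seq_len(n - 1L), function(i)
                       fragmentMz(seq, s, i, charge, mods), numeric(1)),
                   stringsAsFactors = FALSE)))
}

#' Annotate a spectrum with theoretical fragment ions
#'
#' Greedily matches theoretical product ions of a peptide to observed peaks:
#' candidate (ion, peak) pairs within \code{tol} are assigned in order of
#' increasing absolute m/z error, each peak and each ion used at most once.
#'
#' @param spectrum a [Spectrum-class].
#' @param seq peptide sequence the spectrum is annotated against.
#' @param tol matching tolerance in Th.
#' @param series fragment series to consider.
#' @param charge fragment charge(s) to consider.
#' @param mods fixed modifications.
#' @return A list with \code{matches} (data.frame: series, index, charge,
#'   theoMz, obsMz, intensity, deltaMz) and \code{byFraction}, the fraction
#'   of theoretical b/y ions found.
#' @export
annotateSpectrum <- function(spectrum, seq, tol = 0.3,
                             series = c("b", "y", "a", "z"), charge = 1L,
                             mods = list()) {
    stopifnot(is(spectrum, "Spectrum"), tol > 0)
    theo <- do.call(rbind, lapply(charge, function(z)
        fragmentLadder(seq, series = series, charge = z, mods = mods)))
    obs <- spectrum@mz
    empty <- data.frame(series = character(), index = integer(),
                        charge = integer(), theoMz = numeric(),
                        obsMz = numeric(), intensity = numeric(),
                        deltaMz = numeric())
    if (!length(obs) || !nrow(theo))
        return(list(matches = empty, byFraction = 0))
    # all candidate pairs within tol, best-error-first greedy assignment
    cand <- do.call(rbind, lapply(seq_len(nrow(theo)), function(i) {
        d <- obs - theo$mz[i]
        k <- which(abs(d) <= tol)
        if (!length(k)) return(NULL)
        data.frame(ion = i, peak = k, err = abs(d[k]))
    }))
    if (is.null(cand)) return(list(matches = empty, byFraction = 0))
    cand <- cand[order(cand$err), , drop = FALSE]
    usedIon <- logical(nrow(theo)); usedPeak <- logical(length(obs))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (!usedIon[cand$ion[i]] && !usedPeak[cand$peak[i]]) {
            keep[i] <- TRUE
            usedIon[cand$ion[i]] <- TRUE
            usedPeak[cand$peak[i]] <- TRUE
        }
    }
    cand <- cand[keep, , drop = FALSE]
    matches <- data.frame(series = theo$series[cand$ion],
                          index = theo$index[cand$ion],
                          charge = theo$charge[cand$ion],
                          theoMz = theo$mz[cand$ion],
                          obsMz = obs[cand$peak],
                          intensity = spectrum@intensity[cand$peak],
                          deltaMz = obs[cand$peak] - theo$mz[cand$ion],
                          stringsAsFactors = FALSE)
    matches <- matches[order(matches$series, matches$index), , drop = FALSE]
    rownames(matches) <- NULL
    by <- theo[theo$series %in% c("b", "y"), , drop = FALSE]
    byHit <- sum(usedIon[as.integer(rownames(by))])
    list(matches = matches,
         byFraction = if (nrow(by)) byHit / nrow(by) else 0)
}
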