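#' Construct a centroided spectrum
#'
#' @param mz fragment m/z values (Th); re-sorted ascending if needed.
#' @param intensity fragment intensities, parallel to \code{mz}.
#' @param precursorMz precursor m/z (Th).
#' @param precursorCharge precursor charge state.
#' @param id spectrum title.
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum(c(147.11, 204.13), c(100, 80), precursorMz = 500.3,
#'          precursorCharge = 2, id = "demo")
#' @export
Spectrum <- function(mz, intensity = rep(1, length(mz)), precursorMz,
                     precursorCharge = 1L, id = "") {
    o <- order(mz)
    new("Spectrum", mz = as.numeric(mz[o]),
        intensity = as.numeric(intensity[o]),
        precursorMz = as.numeric(precursorMz),
        precursorCharge = as.integer(precursorCharge), id = as.character(id))
}

#' @rdname accessors
#' @export
setMethod("peakMz", "Spectrum", function(x) x@mz)

#' @rdname accessors
#' @export
setMethod("peakIntensity", "Spectrum", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)

#' @rdname accessors
#' @export
setMethod("precursorCharge", "Spectrum", function(x) x@precursorCharge)

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum '%s': precursor %.4f Th (+%d), %d peaks\n",
                object@id, object@precursorMz, object@precursorCharge,
                length(object@mz)))
})

#' Read and write Mascot generic format (MGF)
#'
#' Minimal MGF support: BEGIN IONS/END IONS blocks with PEPMASS, CHARGE and
#' TITLE headers and whitespace-separated peak lines. Charges are read as
#' positive-mode values ("2+" or "2").
#'
#' @param path file path.
#' @return \code{readMGF} returns a list of [Spectrum-class] objects.
#' @export
readMGF <- function(path) {
    lines <- readLines(path)
    starts <- grep("^BEGIN IONS", lines)
    ends <- grep("^END IONS", lines)
    if (length(starts) != length(ends))
        stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
    lapply(seq_along(starts), function(i) {
        block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
        hdr <- grepl("=", block, fixed = TRUE)
        keyval <- strsplit(block[hdr], "=", fixed = TRUE)
        keys <- toupper(vapply(keyval, `[`, "", 1L))
        vals <- vapply(keyval, function(x) paste(x[-1], collapse = "="), "")
        pep <- as.numeric(strsplit(trimws(vals[keys == "PEPMASS"]), "\\s+")[[1]][1])
        ch <- if (any(keys == "CHARGE"))
            as.integer(sub("\\+$", "", trimws(vals[keys == "CHARGE"][1]))) else 1L
        title <- if (any(keys == "TITLE")) vals[keys == "TITLE"][1] else ""
        pk <- block[!hdr & nzchar(trimws(block))]
        if (length(pk)) {
            m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"),
                                       function(x) as.numeric(x[1:2])))
            Spectrum(m[, 1], m[, 2], pep, ch, title)
        } else Spectrum(numeric(), numeric(), pep, ch, title)
    })
}

#' @rdname readMGF
#' @param spectra list of [Spectrum-class] objects.
#' @export
writeMGF <- function(spectra, path) {
    if (is(spectra, "Spectrum")) spectra <- list(spectra)
    con <- file(path, "w")
    on.exit(close(con))
    for (sp in spectra) {
        writeLines(c("BEGIN IONS",
                     sprintf("TITLE=%s", sp@id),
                     sprintf("PEPMASS=%.6f", sp@precursorMz),
                     sprintf("CHARGE=%d+", sp@precursorCharge),
                     sprintf("%.6f %.6f", sp@mz, sp@intensity),
                     "END IONS"), con)
    }
    invisible(path)
}
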