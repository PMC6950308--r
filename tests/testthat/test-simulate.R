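test_that("generators are deterministic for a fixed seed", {
    t1 <- simulateTranscriptome("MKTAYIAKQR", nDecoys = 5, seed = 3)
    t2 <- simulateTranscriptome("MKTAYIAKQR", nDecoys = 5, seed = 3)
    expect_identical(t1, t2)
    p1 <- tempfile(fileext = ".mgf"); p2 <- tempfile(fileext = ".mgf")
    writeMGF(simulateSpectra("MKTAYIAKQRDDFE", seed = 4)$spectra, p1)
    writeMGF(simulateSpectra("MKTAYIAKQRDDFE", seed = 4)$spectra, p2)
    expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
    a1 <- simulateInhibitionAssay(1.6, 0.5, 100, 100, c(1, 2, 4, 8, 16),
                                  cv = 0.05, seed = 5)
    a2 <- simulateInhibitionAssay(1.6, 0.5, 100, 100, c(1, 2, 4, 8, 16),
                                  cv = 0.05, seed = 5)
    expect_identical(a1@rate, a2@rate)
})

test_that("the planted contig translates to the planted protein", {
    protein <- atpiSequences()[["ATPI_II"]]
    tx <- simulateTranscriptome(protein, nDecoys = 10, seed = 6)
    frames <- sixFrameTranslate(tx$contigs[[tx$manifest$plantedId]])
    expect_true(any(grepl(protein, frames, fixed = TRUE)))
    # the upstream in-frame stop makes the ORF segment the exact protein
    segs <- candidateProteins(tx$contigs[tx$manifest$plantedId],
                              minLength = 20)
    expect_true(protein %in% segs)
})

test_that("decoy contigs avoid all 8-mers of the planted protein", {
    protein <- atpiSequences()[["ATPI_I"]]
    tx <- simulateTranscriptome(protein, nDecoys = 30, seed = 7)
    kmers <- unique(substring(protein, 1:(nchar(protein) - 7),
                              8:nchar(protein)))
    decoys <- tx$contigs[names(tx$contigs) != tx$manifest$plantedId]
    for (d in decoys) {
        frames <- sixFrameTranslate(d)
        expect_false(any(vapply(kmers, function(k)
            any(grepl(k, frames, fixed = TRUE)), TRUE)))
    }
})

test_that("noiseless synthetic spectra self-annotate completely", {
    sim <- simulateSpectra("MKTAYIAKQRDDFECK", maxMissed = 0, minLength = 4,
                           seed = 8)
    for (i in seq_along(sim$spectra)) {
        ann <- annotateSpectrum(sim$spectra[[i]],
                                sim$manifest$sequence[i], tol = 0.3,
                                series = c("b", "y"),
                                mods = list(modCAM()))
        expect_equal(ann$byFraction, 1)
    }
})

test_that("jittered ladders are still annotated at the working tolerance", {
    sim <- simulateSpectra(atpiSequences()[["ATPI_I"]], mzJitterSD = 0.1,
                           nDecoyPeaks = 10, seed = 9)
    fractions <- vapply(seq_along(sim$spectra), function(i)
        annotateSpectrum(sim$spectra[[i]], sim$manifest$sequence[i],
                         tol = 0.3, series = c("b", "y"),
                         mods = list(modCAM()))$byFraction, numeric(1))
    expect_gte(mean(fractions), 0.95)
})

test_that("the precursor charge model spans 1 to 5", {
    expect_equal(chargeModel(c(3, 14, 21, 35, 100)), c(1L, 2L, 3L, 5L, 5L))
})

test_that("MGF files round-trip through write and read", {
    sim <- simulateSpectra("MKTAYIAKQR", minLength = 3, nDecoyPeaks = 5,
                           seed = 10)
    path <- tempfile(fileext = ".mgf")
    writeMGF(sim$spectra, path)
    back <- readMGF(path)
    expect_length(back, length(sim$spectra))
    for (i in seq_along(back)) {
        expect_equal(peakMz(back[[i]]), peakMz(sim$spectra[[i]]),
                     tolerance = 1e-5)
        expect_equal(precursorMz(back[[i]]),
                     precursorMz(sim$spectra[[i]]), tolerance = 1e-5)
        expect_equal(precursorCharge(back[[i]]),
                     precursorCharge(sim$spectra[[i]]))
    }
})

test_that("simulated alignments exercise the full score range", {
    aln <- simulateAlignment(nSeqs = 14, nColumns = 52, seed = 11)
    expect_length(aln, 14)
    expect_true(all(nchar(aln) == 52))
    s <- conservationScores(scoreAlignment(aln))
    expect_true(any(s == 11))
    expect_true(any(s <= 1))
    expect_gt(sd(s), 0)
})

test_that("noiseless ddG tables regress to r = 1 and means recover exactly", {
    aln <- simulateAlignment(nSeqs = 6, nColumns = 30, pGap = 0, seed = 12)
    sim <- simulateDdgTables(aln, slope = 0.4, intercept = 0.2,
                             noiseSD = 0, seed = 13)
    md <- meanDdgPerColumn(sim$ddg, aln)
    reg <- conservationStabilityRegression(sim$profile, md)
    if (!reg$degenerate) expect_equal(reg$r, 1)
    expect_equal(md$meanDdg,
                 0.2 + 0.4 * conservationScores(sim$profile))
    expect_true(all(md$n == 6))
})

test_that("clamped ddG values stay inside the requested band", {
    aln <- simulateAlignment(nSeqs = 14, nColumns = 52, seed = 14)
    sim <- simulateDdgTables(aln, targetR = 0.73, clamp = c(-0.2, 5.4),
                             seed = 15)
    expect_true(all(sim$ddg$ddg >= -0.2 & sim$ddg$ddg <= 5.4))
})
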