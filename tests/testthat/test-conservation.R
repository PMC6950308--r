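test_that("identity, gaps, and property counting behave as scored", {
    expect_equal(amasScoreColumn(c("K", "K", "K")), 11L)
    expect_equal(amasScoreColumn(c("K", "-", "K")), 0L)
    expect_equal(amasScoreColumn(c("I", "L", "V")),
                 oracleAmas(c("I", "L", "V"), kunitzPropertyTable()))
    expect_error(amasScoreColumn(c("K", "Z")), "Z")
})

test_that("column scores equal the exhaustive property-count oracle", {
    set.seed(51)
    tab <- kunitzPropertyTable()
    for (i in 1:500) {
        col <- sample(c(AA20, "-"), 3, replace = TRUE,
                      prob = c(rep(1, 20), 2))
        expect_equal(amasScoreColumn(col, tab), oracleAmas(col, tab))
    }
})

test_that("scores are invariant under row permutation and duplication", {
    set.seed(52)
    for (i in 1:50) {
        col <- sample(AA20, 4, replace = TRUE)
        s <- amasScoreColumn(col)
        expect_equal(amasScoreColumn(sample(col)), s)
        expect_equal(amasScoreColumn(c(col, col)), s)
    }
})

test_that("adding a distinct residue never raises a column score", {
    set.seed(53)
    for (i in 1:50) {
        col <- sample(AA20, sample(2:5, 1), replace = TRUE)
        extra <- sample(setdiff(AA20, col), 1)
        expect_lte(amasScoreColumn(c(col, extra)), amasScoreColumn(col))
    }
})

test_that("alignment scoring marks identical and cysteine columns", {
    aln <- c(s1 = "KCVDA", s2 = "KCVDA")
    expect_true(all(conservationScores(scoreAlignment(aln)) == 11L))
    # the two inhibitor chains share all six cysteine columns
    s <- atpiSequences()
    pair <- c(ATPI_I = substr(s[["ATPI_I"]], 3, 60), ATPI_II = s[["ATPI_II"]])
    prof <- scoreAlignment(pair)
    cysCols <- which(strsplit(pair[["ATPI_I"]], "")[[1]] == "C")
    expect_length(cysCols, 6)
    expect_true(all(conservationScores(prof)[cysCols] == 11L))
})

test_that("histograms conserve columns and bins partition the scale", {
    aln <- simulateAlignment(nSeqs = 8, nColumns = 40, seed = 54)
    prof <- scoreAlignment(aln)
    expect_equal(sum(scoreHistogram(prof)), 40)
    bins <- binScores(prof)
    expect_equal(length(bins), 40)
    expect_false(anyNA(bins))
    tallied <- table(bins)
    for (b in names(tallied)) {
        rng <- as.integer(strsplit(b, "-")[[1]])
        expect_equal(unname(tallied[[b]]),
                     sum(conservationScores(prof) >= rng[1] &
                         conservationScores(prof) <= rng[2]))
    }
    expect_error(binScores(prof, bins = list(c(0, 5), c(5, 11))), "partition")
})

test_that("ddG averaging maps positions through gaps and flags missing", {
    aln <- c(h1 = "AC-DE", h2 = "ACFDE")
    ddg <- data.frame(homolog = c("h1", "h1", "h2", "h2", "h2"),
                      position = c(1, 3, 1, 3, 5),
                      ddg = c(1, 2, 3, 4, 5))
    md <- meanDdgPerColumn(ddg, aln)
    expect_equal(md$meanDdg, c(2, NA, 4, 2, 5))
    expect_equal(md$n, c(2L, 0L, 1L, 1L, 1L))
    expect_error(meanDdgPerColumn(
        data.frame(homolog = "h1", position = 9, ddg = 1), aln), "length")
})

test_that("regression recovers exact lines, signs, and affine invariance", {
    scores <- c(0, 2, 4, 6, 8, 10, 11)
    exact <- 0.5 + 0.3 * scores
    r1 <- conservationStabilityRegression(scores, exact)
    expect_equal(r1$r, 1)
    expect_equal(r1$slope, 0.3)
    expect_equal(r1$intercept, 0.5)
    r2 <- conservationStabilityRegression(scores, -exact)
    expect_lt(r2$r, 0)
    set.seed(55)
    noisy <- exact + rnorm(7, 0, 0.4)
    a <- conservationStabilityRegression(scores, noisy)
    b <- conservationStabilityRegression(scores, 3 + 7 * noisy)
    expect_equal(abs(a$r), abs(b$r))
    flat <- conservationStabilityRegression(scores, rep(1, 7))
    expect_true(flat$degenerate)
    expect_true(is.na(flat$r))
})
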