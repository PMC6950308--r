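toyTrajectory <- function(nFrames = 5, nAtoms = 10, seed = 1) {
    set.seed(seed)
    coords <- array(rnorm(nFrames * nAtoms * 3, sd = 5),
                    dim = c(nFrames, nAtoms, 3))
    atoms <- data.frame(name = "CA", element = "C", resno = seq_len(nAtoms),
                        resname = "ALA", chain = "A")
    Trajectory(coords, atoms)
}

rotationMatrix <- function(axis, theta) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

test_that("superposition removes rigid motion exactly", {
    tr <- toyTrajectory(nFrames = 1)
    ref <- frameCoords(tr, 1)
    moved <- ref %*% rotationMatrix(c(1, 2, 3), 0.7)
    moved <- sweep(moved, 2, c(10, -4, 2), "+")
    both <- Trajectory(array(c(rbind(as.vector(ref), as.vector(moved))),
                             dim = c(2, nrow(ref), 3)), atomTable(tr))
    aligned <- superposeFrames(both, reference = 1, selection = 1:10)
    expect_equal(attr(aligned, "rmsd"), c(0, 0), tolerance = 1e-8)
    expect_equal(frameCoords(aligned, 2), ref, tolerance = 1e-8)
    expect_error(superposeFrames(both, selection = 1:2), ">= 3")
})

test_that("superposition RMSD matches the quaternion oracle", {
    set.seed(71)
    for (rep in 1:10) {
        ref <- matrix(rnorm(30, sd = 3), 10, 3)
        mob <- matrix(rnorm(30, sd = 3), 10, 3)
        both <- Trajectory(array(c(rbind(as.vector(ref), as.vector(mob))),
                                 dim = c(2, 10, 3)),
                           data.frame(name = "CA", element = "C",
                                      resno = 1:10, resname = "ALA",
                                      chain = "A"))
        aligned <- superposeFrames(both, reference = 1, selection = 1:10)
        expect_equal(attr(aligned, "rmsd")[2], oracleSuperposeRMSD(mob, ref),
                     tolerance = 1e-8)
    }
})

test_that("a static trajectory has zero RMSF", {
    ref <- simulateReferenceStructure(c(A = "ACDEFG"))
    tr <- simulateTrajectory(ref, amplitudes = 0, nFrames = 20, seed = 1)
    prof <- rmsf(tr)
    expect_equal(prof$rmsf, rep(0, 6))
    expect_error(rmsf(tr, window = integer()), "window")
})

test_that("RMSF is invariant under a global rigid motion of all frames", {
    ref <- simulateReferenceStructure(c(A = "ACDEFGHIKL"))
    tr <- simulateTrajectory(ref, amplitudes = 0.4, nFrames = 100, seed = 2)
    base <- rmsf(tr)$rmsf
    R <- rotationMatrix(c(0, 1, 1), 1.1)
    moved <- tr@coords
    for (f in seq_len(nFrames(tr)))
        moved[f, , ] <- sweep(tr@coords[f, , ] %*% R, 2, c(5, 5, 5), "+")
    expect_equal(rmsf(Trajectory(moved, atomTable(tr)))$rmsf, base,
                 tolerance = 1e-10)
})

test_that("RMSF orders residues by their fluctuation amplitude", {
    amps <- c(0.2, 0.2, 0.8, 0.8, 0.2, 0.2)   # a mobile loop in the middle
    ref <- simulateReferenceStructure(c(A = "ACDEFG"))
    tr <- simulateTrajectory(ref, amplitudes = amps, nFrames = 400, seed = 3)
    prof <- rmsf(tr)
    expect_true(min(prof$rmsf[3:4]) > max(prof$rmsf[c(1, 2, 5, 6)]))
})

test_that("hydrogen-bond occupancy counts frames exactly", {
    ref <- simulateReferenceStructure(c(A = "N", B = "S"))
    don <- which(atomTable(ref)$chain == "A" & atomTable(ref)$name == "N")
    acc <- which(atomTable(ref)$chain == "B" & atomTable(ref)$name == "O")
    tr <- simulateTrajectory(ref, amplitudes = 0, nFrames = 1000, seed = 4,
                             hbond = list(donor = don, acceptor = acc,
                                          occupancy = 0.85))
    rep <- hbondOccupancy(tr, dCut = 3.5, intermolecular = TRUE)
    row <- rep[rep$occupancy > 0.5, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$occupancy, 0.85)
    expect_equal(as.character(row$class), "strong")
    # a pair fixed at bonding distance in every frame
    always <- simulateTrajectory(ref, amplitudes = 0, nFrames = 50, seed = 5,
                                 hbond = list(donor = don, acceptor = acc,
                                              occupancy = 1))
    rep2 <- hbondOccupancy(always, dCut = 3.5)
    expect_equal(max(rep2$occupancy), 1)
})

test_that("occupancies equal the naive per-frame oracle", {
    ref <- simulateReferenceStructure(c(A = "GN", B = "QS"), chainOffset = 6)
    tr <- simulateTrajectory(ref, amplitudes = 1.5, nFrames = 60, seed = 6)
    rep <- hbondOccupancy(tr, dCut = 3.5, intermolecular = TRUE,
                          minOccupancy = 0)
    a <- atomTable(tr)
    lbl <- function(i) sprintf("%s%d-%s%s", a$chain[i], a$resno[i],
                               c(GLY = "G", ASN = "N", GLN = "Q",
                                 SER = "S")[a$resname[i]], a$name[i])
    for (k in seq_len(nrow(rep))) {
        d <- which(vapply(seq_len(nrow(a)), lbl, "") == rep$donor[k])
        ac <- which(vapply(seq_len(nrow(a)), lbl, "") == rep$acceptor[k])
        expect_equal(rep$occupancy[k], oraclePairOccupancy(tr, d, ac, 3.5))
    }
})

test_that("close contacts respect the cutoff and are chain-symmetric", {
    atoms <- data.frame(name = "CA", element = "C", resno = c(1, 1),
                        resname = "ALA", chain = c("A", "B"))
    near <- Trajectory(array(c(0, 3.9, 0, 0, 0, 0), dim = c(1, 2, 3)),
                       atoms)
    expect_equal(nrow(closeContacts(near)), 1L)
    far <- Trajectory(array(c(0, 4.1, 0, 0, 0, 0), dim = c(1, 2, 3)), atoms)
    expect_equal(nrow(closeContacts(far)), 0L)
    expect_error(closeContacts(Trajectory(
        array(0, dim = c(1, 1, 3)),
        data.frame(name = "CA", element = "C", resno = 1, resname = "ALA",
                   chain = "A"))), "chains")
})

test_that("a designed interface is recovered from contact occupancy", {
    # CA-only two-chain system; residues 4-6 of B sit 3 A from 4-6 of A,
    # all other inter-chain pairs are > 4 A apart
    atoms <- data.frame(name = "CA", element = "C",
                        resno = rep(1:10, 2), resname = "ALA",
                        chain = rep(c("A", "B"), each = 10))
    y <- c(rep(0, 10), ifelse(1:10 %in% 4:6, 3, 50))
    coords <- array(c(rep(3.8 * (1:10), 2), y, rep(0, 20)),
                    dim = c(1, 20, 3))
    moved <- Trajectory(coords, atoms)
    tr <- simulateTrajectory(moved, amplitudes = 0.05, nFrames = 40,
                             seed = 7)
    cc <- closeContacts(tr, cutoff = 4.0)
    strong <- cc[cc$occupancy > 0.5, ]
    expect_setequal(unique(strong$resnoA), 4:6)
    expect_setequal(unique(strong$resnoB), 4:6)
    expect_true(all(cc$occupancy >= 0 & cc$occupancy <= 1))
})

test_that("mean H-bonds per frame equals the sum of pair occupancies", {
    ref <- simulateReferenceStructure(c(A = "GN", B = "QS"), chainOffset = 6)
    tr <- simulateTrajectory(ref, amplitudes = 1.2, nFrames = 80, seed = 8)
    rep <- hbondOccupancy(tr, dCut = 3.5, intermolecular = TRUE)
    don <- KunitzChar:::.hbRole(atomTable(tr), KunitzChar:::.HB_DONORS)
    acc <- KunitzChar:::.hbRole(atomTable(tr), KunitzChar:::.HB_ACCEPTORS)
    a <- atomTable(tr)
    perFrame <- vapply(seq_len(nFrames(tr)), function(f) {
        x <- frameCoords(tr, f)
        n <- 0L
        for (d in don) for (ac in acc) {
            if (a$chain[d] == a$chain[ac]) next
            if (sqrt(sum((x[d, ] - x[ac, ])^2)) <= 3.5) n <- n + 1L
        }
        n
    }, integer(1))
    expect_equal(mean(perFrame), sum(rep$occupancy))
})

test_that("multi-model PDB round-trips through write and read", {
    ref <- simulateReferenceStructure(c(A = "ACD", B = "GKL"))
    tr <- simulateTrajectory(ref, amplitudes = 0.3, nFrames = 3, seed = 9)
    path <- tempfile(fileext = ".pdb")
    writeTrajectoryPDB(tr, path)
    back <- readTrajectoryPDB(path)
    expect_equal(nFrames(back), 3)
    expect_equal(nAtoms(back), nAtoms(tr))
    expect_equal(back@coords, tr@coords, tolerance = 1e-3)
    expect_equal(atomTable(back)$resno, atomTable(tr)$resno)
    expect_equal(atomTable(back)$chain, atomTable(tr)$chain)
})
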