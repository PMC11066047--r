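test_that("PDB loading keeps Calpha residues and flags absent ones", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(miniPdbLines(), f)
    s <- loadStructure(f)
    a <- structureAtoms(s)
    expect_equal(nrow(a), 3L)        # water ignored, chain kept
    expect_equal(a$present, c(TRUE, TRUE, FALSE))
    expect_equal(a$resname, c("ALA", "GLY", "SER"))
})

test_that("mmCIF and PDB serializations give identical models", {
    fp <- withr::local_tempfile(fileext = ".pdb")
    fc <- withr::local_tempfile(fileext = ".cif")
    writeLines(miniPdbLines(), fp)
    writeLines(miniCifLines(), fc)
    expect_identical(structureAtoms(loadStructure(fp)),
                     structureAtoms(loadStructure(fc)))
})

test_that("unreadable or empty structures are format errors", {
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(c("REMARK nothing here", "END"), f)
    expect_error(loadStructure(f), "")
    expect_error(loadStructure("/nonexistent/file.pdb"), "not found")
})

test_that("chain assignment recovers identity, offsets and deletions", {
    seqStr <- "MKAVLKDGKTRLAEKW"
    aa3 <- bio3d::aa123(strsplit(seqStr, "")[[1]])
    n <- nchar(seqStr)
    # identical chain numbered 1..N
    s1 <- StructureModel("m1", chain = "A", resno = 1:n, resname = aa3,
                         x = seq_len(n) * 3.8, y = 0, z = 0)
    asg <- buildChainAssignment(s1, c(PX = seqStr))
    cp <- asg@assignments$PX[[1]]
    expect_equal(cp$identity, 1.0)
    expect_equal(unname(cp$map[as.character(1:n)]), 1:n)
    # same chain renumbered +5
    s2 <- StructureModel("m2", chain = "A", resno = 1:n + 5L, resname = aa3,
                         x = seq_len(n) * 3.8, y = 0, z = 0)
    cp2 <- buildChainAssignment(s2, c(PX = seqStr))@assignments$PX[[1]]
    expect_equal(unname(cp2$map[as.character(1:n)]), 1:n + 5L)
    # internal 3-residue deletion: map skips the gap, identity (N-3)/N
    del <- c(1:6, 10:n)
    s3 <- StructureModel("m3", chain = "A", resno = seq_along(del),
                         resname = aa3[del],
                         x = seq_along(del) * 3.8, y = 0, z = 0)
    cp3 <- buildChainAssignment(s3, c(PX = seqStr),
                                minIdentity = 0.5)@assignments$PX[[1]]
    expect_equal(cp3$identity, (n - 3) / n)
    expect_false(any(c("7", "8", "9") %in% names(cp3$map)))
    expect_equal(unname(cp3$map[as.character(10:n)]), 7:(n - 3))
})

test_that("chains below the identity threshold stay unassigned", {
    s <- StructureModel("m", chain = "A", resno = 1:10,
                        resname = bio3d::aa123(rep("A", 10)),
                        x = 1:10, y = 0, z = 0)
    expect_warning(
        asg <- buildChainAssignment(s, c(PX = "WWWWWWWWWW")),
        "minIdentity")
    expect_length(asg@assignments, 0L)
    expect_equal(asg@unassigned, "A")
})

test_that("Calpha distances are Euclidean, symmetric, and error on absences", {
    s <- tinyStructure()
    expect_equal(caDistance(s, list("A", 1), list("A", 1)), 0)
    expect_equal(caDistance(s, list("A", 1), list("A", 2)), 5)  # 3-4-5
    expect_equal(caDistance(s, list("A", 2), list("A", 1)), 5)
    expect_error(caDistance(s, list("A", 1), list("A", 3)), "residue 3")
    # brute-force oracle on random coordinates
    set.seed(5)
    xyz <- matrix(rnorm(60), 20L)
    sr <- StructureModel("r", chain = "A", resno = 1:20, resname = "ALA",
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    for (k in 1:25) {
        ij <- sample.int(20L, 2L)
        manual <- sqrt((xyz[ij[1], 1] - xyz[ij[2], 1])^2 +
                       (xyz[ij[1], 2] - xyz[ij[2], 2])^2 +
                       (xyz[ij[1], 3] - xyz[ij[2], 3])^2)
        expect_equal(caDistance(sr, list("A", ij[1]), list("A", ij[2])),
                     manual, tolerance = 1e-12)
    }
})

test_that("homo-oligomer mapping takes the minimum over copy pairs", {
    # protein PX twice (chains A, B), protein PY once (chain C); the
    # B-copy of residue 1 sits far away, so the A-copy pairing must win
    seqX <- "KAVK"; seqY <- "GKLG"
    aaX <- bio3d::aa123(strsplit(seqX, "")[[1]])
    aaY <- bio3d::aa123(strsplit(seqY, "")[[1]])
    s <- StructureModel("dimer",
        chain = rep(c("A", "B", "C"), each = 4L), resno = rep(1:4, 3L),
        resname = c(aaX, aaX, aaY),
        x = c(0, 3.8, 7.6, 11.4,   100, 103.8, 107.6, 111.4,   0, 3.8, 7.6, 11.4),
        y = c(rep(0, 8), rep(12.3, 4)), z = 0)
    asg <- buildChainAssignment(s, c(PX = seqX, PY = seqY))
    expect_length(asg@assignments$PX, 2L)
    tab <- CrossLinkTable("PX", 1L, "PY", 1L)
    m <- mapCrossLinks(tab, s, asg)
    expect_equal(m$status, "mapped")
    expect_equal(m$chainA, "A")           # nearer copy chosen
    expect_equal(m$distance, 12.3)
    # min-rule dominance: the chosen distance is <= every enumerated pair
    dAll <- c(12.3, sqrt(100^2 + 12.3^2))
    expect_true(all(m$distance <= dAll))
})

test_that("failure modes are encoded as statuses, not errors", {
    s <- tinyStructure()
    asg <- new("ChainAssignment", assignments = list(
        PX = list(list(chain = "A",
                       map = c(`1` = 1L, `2` = 2L, `3` = 3L),
                       identity = 1))), unassigned = character())
    m <- mapCrossLinks(CrossLinkTable(c("PX", "PX", "QQ"), c(1L, 1L, 1L),
                                      c("PX", "PX", "QQ"), c(2L, 3L, 5L)),
                       s, asg)
    expect_equal(m$status, c("mapped", "endpoint_missing", "protein_absent"))
    expect_equal(is.na(m$distance), c(FALSE, TRUE, TRUE))
})

test_that("satisfaction reports count over mapped links only", {
    # 16 mapped links, 14 within the restraint
    d <- c(rep(20, 14), 40, 50)
    mapped <- S4Vectors::DataFrame(status = rep("mapped", 16), distance = d)
    rep <- satisfactionReport(mapped, maxDistance = 35)
    expect_equal(rep@nSatisfied, 14L)
    expect_equal(agreement(rep), 0.875)
    # empty input: agreement undefined, not zero
    empty <- satisfactionReport(
        S4Vectors::DataFrame(status = character(), distance = numeric()))
    expect_equal(empty@nInput, 0L)
    expect_true(is.na(agreement(empty)))
    # boundary inclusive: exactly 35 satisfies
    atEdge <- satisfactionReport(
        S4Vectors::DataFrame(status = "mapped", distance = 35))
    expect_equal(atEdge@nSatisfied, 1L)
})

test_that("raising the restraint never decreases the satisfied count", {
    set.seed(9)
    mapped <- S4Vectors::DataFrame(status = rep("mapped", 200),
                                   distance = runif(200, 0, 80))
    ns <- vapply(seq(5, 80, by = 5), function(mx)
        satisfactionReport(mapped, mx)@nSatisfied, 0L)
    expect_true(all(diff(ns) >= 0))
})

test_that("distance histograms use left-closed right-open bins from 0", {
    h <- distanceDistribution(c(5, 5, 12), binWidth = 10)
    expect_equal(h$counts, c(2L, 1L))
    expect_equal(h$breaks, c(0, 10, 20))
    # a value on an edge falls in the bin to its right
    h2 <- distanceDistribution(10, binWidth = 10)
    expect_equal(h2$counts, c(0L, 1L))
    # per-value loop oracle on random distances
    set.seed(17)
    d <- runif(300, 0, 60)
    h3 <- distanceDistribution(d, binWidth = 7)
    oracle <- integer(length(h3$counts))
    for (v in d) {
        b <- floor(v / 7) + 1L
        oracle[b] <- oracle[b] + 1L
    }
    expect_equal(h3$counts, oracle)
    expect_equal(sum(h3$counts), 300L)
})
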