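test_that("parsing reads back a small TSV and canonicalizes endpoints", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("ProteinA\tLysA\tProteinB\tLysB",
                 "P2\t10\tP1\t20",
                 "P1\t10\tP1\t10",
                 "P1\t5\tP2\t7"), f)
    tab <- parseCrossLinkTable(f, columnMap = list(
        proteinA = "ProteinA", residueA = "LysA",
        proteinB = "ProteinB", residueB = "LysB"))
    expect_equal(nLinks(tab), 3L)
    rec <- linkRecords(tab)
    # reported orientation P2-P1 is stored canonically as P1-P2
    expect_equal(rec$proteinA[1], "P1")
    expect_equal(rec$residueA[1], 20L)
    expect_equal(rec$proteinB[1], "P2")
    # degenerate self-pair accepted
    expect_equal(rec$residueA[2], 10L)
    expect_equal(rec$residueB[2], 10L)
})

test_that("parser errors name the missing column and the bad line", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("protein_a,residue_a,protein_b,residue_b",
                 "P1,10,P2,xx"), f)
    expect_error(
        parseCrossLinkTable(f, columnMap = list(residueB = "nope")),
        "nope")
    expect_error(parseCrossLinkTable(f), "line.*1")
})

test_that("multi-accession endpoint fields take the first accession", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("protein_a\tresidue_a\tprotein_b\tresidue_b",
                 "P1;P9\t4\tP2\t8"), f)
    expect_warning(tab <- parseCrossLinkTable(f), "multi-accession")
    expect_equal(linkRecords(tab)$proteinA, "P1")
    expect_equal(attr(tab, "multiAccessionRows"), 1L)
})

test_that("percent-dialect FDR columns are auto-rescaled to fractions", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("protein_a\tresidue_a\tprotein_b\tresidue_b\tfdr",
                 "P1\t4\tP2\t8\t2", "P1\t5\tP2\t9\t0.5"), f)
    tab <- parseCrossLinkTable(f)
    expect_equal(linkRecords(tab)$fdr, c(0.02, 0.005))
})

test_that("write -> parse -> write round-trips byte-identically", {
    set.seed(41)
    raw <- randomRawLinks(100)
    tab <- CrossLinkTable(raw$pa, raw$ra, raw$pb, raw$rb,
                          score = round(runif(100), 3),
                          fdr = round(runif(100, 0, 0.05), 4))
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeCrossLinkTable(tab, f1)
    back <- parseCrossLinkTable(f1)
    expect_equal(as.data.frame(linkRecords(back)),
                 as.data.frame(linkRecords(tab)))
    writeCrossLinkTable(back, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("FDR filtering is inclusive at the threshold", {
    tab <- CrossLinkTable(c("A", "B", "C"), 1:3, c("D", "E", "F"), 4:6,
                          fdr = c(0.01, 0.02, 0.03))
    kept <- filterFDR(tab, 0.02)
    expect_equal(nLinks(kept), 2L)
    expect_equal(kept@fdrThreshold, 0.02)
    expect_equal(nLinks(filterFDR(tab, 1.0)), 3L)
    # planted distribution matches a brute-force scan
    set.seed(7)
    fdr <- runif(500, 0, 0.1)
    big <- CrossLinkTable(sprintf("P%03d", 1:500), 1:500,
                          sprintf("Q%03d", 1:500), 1:500, fdr = fdr)
    expect_equal(nLinks(filterFDR(big, 0.02)), sum(fdr <= 0.02))
})

test_that("records without FDR error unless explicitly kept", {
    tab <- CrossLinkTable(c("A", "B"), 1:2, c("D", "E"), 3:4,
                          fdr = c(0.01, NA))
    expect_error(filterFDR(tab, 0.02), "lack an fdr")
    kept <- filterFDR(tab, 0.02, keepMissing = TRUE)
    expect_equal(nLinks(kept), 2L)
    expect_equal(attr(kept, "nMissingFdr"), 1L)
})

test_that("deduplication collapses orientation-symmetric rows and sums CSMs", {
    tab <- CrossLinkTable(c("A", "B"), c(10L, 20L), c("B", "A"), c(20L, 10L),
                          csmCount = c(1L, 1L))
    ded <- deduplicateUniquePairs(tab)
    expect_equal(nLinks(ded), 1L)
    expect_equal(linkRecords(ded)$csmCount, 2L)
    expect_true(isDeduplicated(ded))
})

test_that("deduplication matches a hash-set oracle and is idempotent", {
    set.seed(13)
    raw <- randomRawLinks(400, nProteins = 4L, maxRes = 12L)
    tab <- CrossLinkTable(raw$pa, raw$ra, raw$pb, raw$rb, csmCount = 1L)
    ded <- deduplicateUniquePairs(tab)
    rec <- linkRecords(tab)
    key <- paste(rec$proteinA, rec$residueA, rec$proteinB, rec$residueB)
    expect_equal(nLinks(ded), length(unique(key)))
    dedRec <- linkRecords(ded)
    dedKey <- paste(dedRec$proteinA, dedRec$residueA, dedRec$proteinB,
                    dedRec$residueB)
    expect_equal(dedRec$csmCount[match(names(table(key)), dedKey)],
                 as.integer(table(key)))
    expect_equal(as.data.frame(linkRecords(deduplicateUniquePairs(ded))),
                 as.data.frame(dedRec))
})

test_that("classification partitions links and counts distinct proteins", {
    one <- deduplicateUniquePairs(CrossLinkTable("P1", 10L, "P1", 10L))
    expect_equal(classifyLinks(one),
                 list(nTotal = 1L, nIntra = 1L, nInter = 0L, nProteins = 1L))
    expect_error(classifyLinks(CrossLinkTable("P1", 1L, "P2", 2L)),
                 "deduplicated")
    # brute-force partition on random mixed tables
    set.seed(23)
    for (rep in 1:5) {
        raw <- randomRawLinks(200, nProteins = 6L, maxRes = 20L)
        ded <- deduplicateUniquePairs(
            CrossLinkTable(raw$pa, raw$ra, raw$pb, raw$rb))
        cls <- classifyLinks(ded)
        rec <- linkRecords(ded)
        expect_equal(cls$nIntra + cls$nInter, cls$nTotal)
        expect_equal(cls$nIntra, sum(rec$proteinA == rec$proteinB))
        expect_equal(cls$nProteins,
                     length(unique(c(rec$proteinA, rec$proteinB))))
    }
})

test_that("summaries are invariant under endpoint orientation", {
    set.seed(31)
    raw <- randomRawLinks(150)
    fwd <- deduplicateUniquePairs(
        CrossLinkTable(raw$pa, raw$ra, raw$pb, raw$rb))
    rev <- deduplicateUniquePairs(
        CrossLinkTable(raw$pb, raw$rb, raw$pa, raw$ra))
    expect_equal(classifyLinks(fwd), classifyLinks(rev))
    expect_equal(as.data.frame(linkRecords(fwd)),
                 as.data.frame(linkRecords(rev)))
})

test_that("invalid records are rejected by the class validity", {
    expect_error(CrossLinkTable("A", 0L, "B", 5L), "residue")
    expect_error(CrossLinkTable("A", 1L, "B", 5L, fdr = 1.5), "fdr")
})
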