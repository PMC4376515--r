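test_that("a delimited matrix with a layout sidecar parses and validates", {
    fx <- writeMatrixFixture()
    x <- readExpressionMatrix(fx$matrix, fx$layout)
    expect_s4_class(x, "ExpressionDataset")
    expect_identical(treatments(x), c("T1", "T2"))
    expect_identical(replicatesOf(x, "T1"), c("R1", "R2"))
    expect_identical(rownames(x), c("g1", "g2", "g3"))
    expect_equal(unname(exprValues(x)["g2", ]), c(5, 6, 2, 2.5))

    # layout can also be passed as a data.frame
    lay <- readLayout(fx$layout)
    expect_identical(readExpressionMatrix(fx$matrix, lay), x)
})

test_that("malformed inputs fail loudly and name the offender", {
    dir <- withr::local_tempdir()
    lay <- data.frame(sample = c("s1", "s2"), treatment = "T1",
                      replicate = c("R1", "R2"))

    dup <- file.path(dir, "dup.tsv")
    writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), dup)
    expect_error(readExpressionMatrix(dup, lay), "gA")

    bad <- file.path(dir, "bad.tsv")
    writeLines(c("gene\ts1\ts2", "g1\t1\tx2"), bad)
    expect_error(readExpressionMatrix(bad, lay), "non-numeric.*s2")

    orphan <- file.path(dir, "orphan.tsv")
    writeLines(c("gene\ts1\ts5", "g1\t1\t2"), orphan)
    expect_error(readExpressionMatrix(orphan, lay), "s5")

    neg <- file.path(dir, "neg.tsv")
    writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t-3\t4"), neg)
    expect_warning(x <- readExpressionMatrix(neg, lay), "g2")
    expect_identical(rownames(x), "g1")
    expect_identical(S4Vectors::metadata(x)$rejectedRows, "g2")
})

test_that("gene length tables validate ids and positivity", {
    dir <- withr::local_tempdir()
    ok <- file.path(dir, "len.tsv")
    writeLines(c("gene\tlength", "g1\t1000", "g2\t2000"), ok)
    expect_identical(readLengthTable(ok), c(g1 = 1000L, g2 = 2000L))

    zero <- file.path(dir, "len0.tsv")
    writeLines(c("gene\tlength", "g1\t0"), zero)
    expect_error(readLengthTable(zero), "g1")

    dup <- file.path(dir, "lend.tsv")
    writeLines(c("gene\tlength", "g1\t1000", "g1\t1500"), dup)
    expect_error(readLengthTable(dup), "duplicate")
})

test_that("write/read round trip preserves values to >= 12 significant digits", {
    x <- simulateExpression(25, 2, 2, replicateNoiseSd = 0.4, seed = 11)
    dir <- withr::local_tempdir()
    p <- file.path(dir, "rt.tsv")
    writeExpressionMatrix(x, p)
    y <- readExpressionMatrix(p, readLayout(paste0(p, ".layout.tsv")))
    expect_equal(exprValues(y), exprValues(x), tolerance = 1e-12)
    expect_identical(sampleLayout(y), sampleLayout(x))
})

test_that("column order never matters: statistics key on (treatment, replicate)", {
    x <- simulateExpression(40, 3, 2, replicateNoiseSd = 0.5, seed = 5)
    perm <- c(4, 1, 6, 3, 2, 5)
    m <- exprValues(x)[, perm]
    lay <- sampleLayout(x)[perm, ]
    y <- ExpressionDataset(m, lay)
    expect_equal(avgDeviation(reproducibility(y)),
                 avgDeviation(reproducibility(x)))
    expect_equal(threshold(fcThreshold(interReplicateFC(y), 0.05)),
                 threshold(fcThreshold(interReplicateFC(x), 0.05)))
})

test_that("comma and semicolon delimiters are auto-detected", {
    dir <- withr::local_tempdir()
    lay <- data.frame(sample = c("s1", "s2"), treatment = "T1",
                      replicate = c("R1", "R2"))
    csv <- file.path(dir, "m.csv")
    writeLines(c("gene,s1,s2", "g1,1,2"), csv)
    expect_equal(unname(exprValues(readExpressionMatrix(csv, lay))[1, ]),
                 c(1, 2))
    scsv <- file.path(dir, "m.scsv")
    writeLines(c("gene;s1;s2", "g1;3;4"), scsv)
    expect_equal(unname(exprValues(readExpressionMatrix(scsv, lay))[1, ]),
                 c(3, 4))
})

test_that("writeReport serializes known result types and rejects others", {
    dir <- withr::local_tempdir()
    x <- simulateExpression(30, 2, 2, replicateNoiseSd = 0.3, seed = 2)
    r <- reproducibility(x)
    p1 <- file.path(dir, "rep.tsv")
    writeReport(r, p1)
    lines <- readLines(p1)
    expect_true(any(grepl("avg_deviation", lines)))
    expect_true(any(grepl("^sourceTreatment", lines)))

    thr <- fcThreshold(interReplicateFC(x), 0.2)
    p2 <- file.path(dir, "thr.txt")
    writeReport(thr, p2, format = "text")
    expect_true(any(grepl("alpha\t0.2", readLines(p2), fixed = TRUE)))

    expect_error(writeReport(list(a = 1), file.path(dir, "x")),
                 "unsupported")
})
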