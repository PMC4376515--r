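test_that("RPKM follows count * 1e9 / (total * length)", {
    m <- cbind(s1 = c(1000, 0, 9000), s2 = c(500, 100, 400))
    rownames(m) <- c("g1", "g2", "g3")
    lay <- data.frame(sample = c("s1", "s2"), treatment = "T1",
                      replicate = c("R1", "R2"))
    x <- ExpressionDataset(m, lay)
    lens <- c(g1 = 1000L, g2 = 500L, g3 = 2000L)
    r <- rpkm(x, lens, totals = c(s1 = 1e6, s2 = 1e6))
    expect_equal(exprValues(r)["g1", "s1"], 1000)
    expect_equal(exprValues(r)["g2", "s1"], 0)
    # library-size cancellation: doubling counts and totals changes nothing
    x2 <- ExpressionDataset(m * 2, lay)
    r2 <- rpkm(x2, lens, totals = c(s1 = 2e6, s2 = 2e6))
    expect_equal(exprValues(r2), exprValues(r))
    # gene order does not matter
    xp <- ExpressionDataset(m[c(3, 1, 2), ], lay)
    rp <- rpkm(xp, lens, totals = c(s1 = 1e6, s2 = 1e6))
    expect_equal(exprValues(rp)[rownames(r), ], exprValues(r))

    expect_error(rpkm(x, lens[1:2]), "g3")
    expect_error(rpkm(x, lens, totals = c(s1 = 0, s2 = 1)), "zero total")
})

test_that("total-count scaling equalizes library sizes and records factors", {
    m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8) * 1e5, 4, 2)
    dimnames(m) <- list(paste0("g", 1:4), c("a", "b"))
    lay <- data.frame(sample = c("a", "b"), treatment = "T1",
                      replicate = c("R1", "R2"))
    x <- ExpressionDataset(m, lay)   # sums 1e6 and 2e6
    s <- totalCountScaling(x)
    f <- S4Vectors::metadata(s)$normalization[[1]]$factors
    expect_equal(unname(f), c(1.5, 0.75))
    expect_equal(unname(colSums(exprValues(s))), rep(1.5e6, 2))

    # already equal sums: factors 1
    y <- ExpressionDataset(matrix(c(1, 2, 2, 1), 2, 2,
                                  dimnames = list(c("g1", "g2"),
                                                  c("a", "b"))),
                           data.frame(sample = c("a", "b"),
                                      treatment = "T1",
                                      replicate = c("R1", "R2")))
    expect_equal(unname(
        S4Vectors::metadata(totalCountScaling(y))$normalization[[1]]$factors),
        c(1, 1))
})

test_that("per-sample scaling repairs the slope but cannot move Pearson r", {
    x <- simulateExpression(400, 1, 2, replicateNoiseSd = 0, seed = 23)
    m <- exprValues(x)
    m[, 2] <- 0.62 * m[, 2]
    b <- ExpressionDataset(m, sampleLayout(x))
    before <- replicateRegression(exprValues(b)[, 1], exprValues(b)[, 2])
    a <- totalCountScaling(b)
    after <- replicateRegression(exprValues(a)[, 1], exprValues(a)[, 2])
    expect_equal(before@slope, 0.62)
    expect_equal(after@slope, 1)
    expect_equal(before@pearsonR, after@pearsonR)
    expect_equal(before@fractionExceeding, 1)
    expect_equal(after@fractionExceeding, 0)
})

test_that("reference-gene scaling anchors each treatment on replicate one", {
    m <- cbind(T1_R1 = c(100, 10, 50), T1_R2 = c(50, 5, 30),
               T2_R1 = c(80, 20, 60), T2_R2 = c(80, 20, 70))
    rownames(m) <- c("ref", "g2", "g3")
    x <- makeDataset(m, 2, 2, geneIds = rownames(m))
    s <- referenceGeneScaling(x, "ref")
    sv <- exprValues(s)
    # T1_R2 multiplied by 100/50 = 2; T2 untouched (ref identical)
    expect_equal(sv[, "T1_R2"], m[, "T1_R2"] * 2)
    expect_equal(sv[, "T2_R2"], m[, "T2_R2"])
    # with a single reference gene its variation is driven to zero
    expect_equal(as.vector(interReplicateVariation(sv["ref", "T1_R1"],
                                                   sv["ref", "T1_R2"])), 0)
    # identical reference values: dataset unchanged
    same <- referenceGeneScaling(
        makeDataset(cbind(c(7, 1), c(7, 3)), 1, 2,
                    geneIds = c("ref", "g")), "ref")
    expect_equal(unname(exprValues(same)[, 2]), c(7, 3))

    expect_error(referenceGeneScaling(x, "nope"), "nope")
    m0 <- m; m0["ref", "T1_R2"] <- 0
    expect_error(referenceGeneScaling(
        makeDataset(m0, 2, 2, geneIds = rownames(m0)), "ref"), "ref")
})

test_that("quantile normalization matches the mean-of-order-statistics rule", {
    m <- cbind(a = c(1, 2, 3), b = c(10, 20, 30))
    x <- ExpressionDataset(matrix(m, 3, 2,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("a", "b"))),
                           data.frame(sample = c("a", "b"),
                                      treatment = "T1",
                                      replicate = c("R1", "R2")))
    q <- quantileNormalize(x)
    expect_equal(unname(exprValues(q)[, "a"]), c(5.5, 11, 16.5))
    expect_equal(unname(exprValues(q)[, "b"]), c(5.5, 11, 16.5))

    # permuted columns come out identical as multisets; idempotent
    y <- simulateExpression(100, 2, 2, replicateNoiseSd = 0.5, seed = 41)
    q1 <- quantileNormalize(y)
    cols <- exprValues(q1)
    for (j in 2:ncol(cols))
        expect_equal(sort(cols[, j]), sort(cols[, 1]), ignore_attr = TRUE)
    q2 <- quantileNormalize(q1)
    expect_equal(exprValues(q2), exprValues(q1))
})

test_that("corrections reduce the variation fraction under pure scale bias", {
    x <- simulateExpression(200, 1, 2, replicateNoiseSd = 0, seed = 19)
    m <- exprValues(x); m[, 2] <- m[, 2] / 1.8
    b <- ExpressionDataset(m, sampleLayout(x))
    fracOf <- function(d) fractionExceeding(interReplicateVariation(
        exprValues(d)[, 1], exprValues(d)[, 2]), 0.5)
    expect_equal(fracOf(b), 1)
    expect_equal(fracOf(totalCountScaling(b)), 0)
    expect_equal(fracOf(quantileNormalize(b)), 0)
    r <- cor(log10(exprValues(b)[, 1]), log10(exprValues(b)[, 2]))
    r2 <- cor(log10(exprValues(totalCountScaling(b))[, 1]),
              log10(exprValues(totalCountScaling(b))[, 2]))
    expect_equal(r, r2)
})
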