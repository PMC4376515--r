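test_that("inter-replicate fold changes pool across pairs with max/min >= 1", {
    x <- makeDataset(cbind(c(10, 10, 30), c(25, 10, 31),
                           c(5, 8, 100), c(5, 9, 105)), 2, 2)
    fc <- interReplicateFC(x)
    expect_equal(length(fc), 6L)           # 2 pairs x 3 genes
    expect_true(all(fc >= 1))
    expect_true(any(abs(fc - 2.5) < 1e-12))  # (10, 25)

    # identical replicates: all fold changes exactly 1
    z <- simulateExpression(20, 2, 2, replicateNoiseSd = 0, seed = 1)
    expect_equal(unique(interReplicateFC(z)), 1)

    # explicit pair selection
    fc1 <- interReplicateFC(x, data.frame(treatment = "T1",
                                          replicate1 = "R1",
                                          replicate2 = "R2"))
    expect_equal(length(fc1), 3L)
})

test_that("the threshold is the smallest observed value below the likelihood", {
    fc <- c(rep(1.1, 90), rep(2.0, 6), rep(4.0, 4))
    r05 <- fcThreshold(fc, 0.05)
    expect_equal(threshold(r05), 4.0)   # P(FC>=2)=0.10 fails, P(FC>=4)=0.04
    r15 <- fcThreshold(fc, 0.15)
    expect_equal(threshold(r15), 2.0)
    expect_false(r05@aboveMax)
    expect_equal(oracleFCThreshold(fc, 0.05), 4.0)
    expect_equal(oracleFCThreshold(fc, 0.15), 2.0)

    expect_error(fcThreshold(numeric(), 0.05), "empty")
    expect_error(fcThreshold(c(0.5, 2), 0.05), ">= 1")
    expect_error(fcThreshold(fc, 1.5), "alpha")
})

test_that("a degenerate distribution yields a flagged above-max threshold", {
    expect_warning(r <- fcThreshold(rep(1, 10), 0.05), "1/alpha")
    expect_true(r@aboveMax)
    expect_gt(threshold(r), 1)
    expect_equal(mean(foldChanges(r) >= threshold(r)), 0)
})

test_that("every output satisfies P(FC >= threshold) < alpha, and alpha ordering holds", {
    set.seed(55)
    for (i in 1:25) {
        fc <- 1 + rexp(sample(30:1000, 1), rate = runif(1, 0.5, 4))
        for (a in c(0.01, 0.05, 0.2)) {
            r <- suppressWarnings(fcThreshold(fc, a))  # small-n warning ok
            expect_lt(mean(fc >= threshold(r)), a)
            orc <- oracleFCThreshold(fc, a)
            if (is.finite(orc)) expect_equal(threshold(r), orc)
            else expect_true(r@aboveMax)
        }
        expect_gte(suppressWarnings(threshold(fcThreshold(fc, 0.01))),
                   suppressWarnings(threshold(fcThreshold(fc, 0.05))))
    }
})

test_that("significant changes at or below the threshold are filtered out", {
    tab <- data.frame(gene = c("a", "b", "c", "d"),
                      fc = c(1.5, 2.0, 3.0, 10),
                      significant = c(TRUE, TRUE, TRUE, FALSE))
    res <- applyThreshold(tab, 2.0)
    expect_equal(res$nSignificant, 3L)
    expect_equal(res$nSubThreshold, 2L)       # 1.5 and the inclusive 2.0
    expect_equal(res$nPassing, 1L)
    expect_equal(res$fractionSubThreshold, 2 / 3)

    expect_equal(applyThreshold(tab, 1.2)$nSubThreshold, 0L)
    empty <- applyThreshold(tab[0, ], 2.0)
    expect_equal(empty$nSignificant, 0L)
    expect_true(is.na(empty$fractionSubThreshold))
    expect_error(applyThreshold(data.frame(gene = "a", fc = 0.5,
                                           significant = TRUE), 2),
                 "convention")
})

test_that("gene-group thresholds follow the group noise structure", {
    # low-abundance genes noisier than high-abundance ones
    set.seed(8)
    nl <- 300; nh <- 300
    low <- exp(rnorm(nl, log(5), 0.3))
    high <- exp(rnorm(nh, log(5000), 0.3))
    base <- c(low, high)
    noisy <- base * exp(rnorm(nl + nh, 0, rep(c(0.8, 0.1), c(nl, nh))))
    x <- makeDataset(cbind(base, noisy), 1, 2)
    grp <- groupedThresholds(x, alpha = 0.05, groupBy = "abundance",
                             bins = c(0, 100, 1e6))
    expect_length(grp, 2L)
    expect_gte(threshold(grp[[1]]), threshold(grp[[2]]))

    # one bin covering everything equals the ungrouped threshold
    one <- groupedThresholds(x, alpha = 0.05, groupBy = "abundance",
                             bins = c(0, 1e6))
    expect_equal(threshold(one[[1]]),
                 threshold(fcThreshold(interReplicateFC(x), 0.05)))

    # length bins need a length table; tiny bins are flagged
    lens <- setNames(rep(c(500L, 5000L), c(nl, nh)), rownames(exprValues(x)))
    expect_error(groupedThresholds(x, 0.05, groupBy = "length",
                                   bins = c(0, 1e4)), "lengths")
    gl <- groupedThresholds(x, 0.05, groupBy = "length",
                            bins = c(0, 1000, 1e4), lengths = lens)
    expect_length(gl, 2L)
})
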