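test_that("population counts follow n(n-1) * r_a * r_b", {
    x4 <- simulateExpression(20, 4, 2, replicateNoiseSd = 0.2, seed = 1)
    p4 <- buildRatioPopulations(x4)
    expect_equal(nrow(populations(p4)), 48L)

    x2 <- simulateExpression(20, 2, 2, replicateNoiseSd = 0.2, seed = 1)
    expect_equal(nrow(populations(buildRatioPopulations(x2))), 8L)

    x3 <- simulateExpression(20, 2, 3, replicateNoiseSd = 0.2, seed = 1)
    expect_equal(nrow(populations(buildRatioPopulations(x3))), 18L)

    x1 <- simulateExpression(20, 1, 2, replicateNoiseSd = 0.2, seed = 1)
    expect_error(buildRatioPopulations(x1), ">= 2 treatments")
})

test_that("statistic ratios compare populations sharing the source replicate", {
    x <- simulateExpression(20, 4, 2, replicateNoiseSd = 0.2, seed = 2)
    r <- statisticRatioDeviations(buildRatioPopulations(x))
    # 12 ordered pairs x 2 source reps x C(2,2 choose)=1 target pair
    expect_equal(length(r@meanDeviations), 24L)
    expect_equal(length(r@sdDeviations), 24L)
    expect_equal(r@nComparisons, 24L)
    cmp <- as.data.frame(comparisons(r))
    expect_true(all(cmp$targetReplicate1 != cmp$targetReplicate2))
})

test_that("the folding rule treats v and 1/v symmetrically", {
    x <- c(0.8, 1.25, 1, 4, 0.25)
    d <- vapply(x, function(v) if (v >= 1) v - 1 else 1 / v - 1, numeric(1))
    expect_equal(d, c(0.25, 0.25, 0, 3, 3))
    # same rule inside the pipeline: relabeling the replicates of a
    # treatment leaves the coefficient unchanged
    y <- simulateExpression(30, 2, 2, replicateNoiseSd = 0.4, seed = 9)
    m <- exprValues(y); lay <- sampleLayout(y)
    swap <- lay
    swap$replicate[swap$treatment == "T2"] <-
        rev(swap$replicate[swap$treatment == "T2"])
    y2 <- ExpressionDataset(m, swap)
    expect_equal(avgDeviation(reproducibility(y2)),
                 avgDeviation(reproducibility(y)))
})

test_that("the hand-enumerated micro example gives pooled mean deviation 0.5", {
    x <- microDataset()
    res <- reproducibility(x)
    # oracle agrees
    orc <- oracleReproducibility(exprValues(x), sampleLayout(x))
    expect_equal(sort(res@meanDeviations), sort(orc$meanDeviations))
    expect_equal(res@meanDeviations[order(res@meanDeviations)],
                 c(0, 0, 1, 1))
    # every S is 0 here, so all SD comparisons are skipped and the pooled
    # coefficient is the mean-deviation average
    expect_equal(res@skipped, 4L)
    expect_equal(avgDeviation(res), 0.5)
    expect_equal(avgDeviation(res), orc$avgDeviation)
})

test_that("identical replicates give exactly zero deviations everywhere", {
    x <- simulateExpression(40, 3, 2, effects = c(1, 2, 0.5),
                            replicateNoiseSd = 0, seed = 4)
    res <- reproducibility(x)
    expect_equal(avgDeviation(res), 0)
    expect_equal(unique(res@meanDeviations), 0)
    w <- withinTreatmentDeviation(x, "T2")
    expect_equal(avgDeviation(w), 0)
    expect_equal(unique(as.data.frame(comparisons(w))$S), 0)
})

test_that("implementation matches the brute-force oracle across random designs", {
    set.seed(2024)
    for (case in seq_len(220)) {
        n <- sample(2:3, 1); r <- sample(2:3, 1); g <- sample(2:5, 1)
        x <- randomDesign(n, r, g)
        res <- reproducibility(x)
        orc <- oracleReproducibility(exprValues(x), sampleLayout(x))
        expect_equal(res@nPopulations, orc$nPopulations)
        expect_equal(length(res@meanDeviations),
                     orc$nComparisonsPerStat)
        expect_equal(res@skipped, orc$skipped)
        expect_equal(sort(res@meanDeviations), sort(orc$meanDeviations))
        expect_equal(sort(res@sdDeviations), sort(orc$sdDeviations))
        expect_equal(avgDeviation(res), orc$avgDeviation)
        expect_equal(sdOfDeviations(res), orc$sdOfDeviations)
    }
})

test_that("coefficients are scale invariant and non-negative", {
    x <- simulateExpression(50, 2, 3, replicateNoiseSd = 0.6, seed = 21)
    res <- reproducibility(x)
    expect_true(all(res@meanDeviations >= 0))
    expect_true(all(res@sdDeviations >= 0))
    y <- ExpressionDataset(exprValues(x) * 37.5, sampleLayout(x))
    expect_equal(avgDeviation(reproducibility(y)), avgDeviation(res))
    expect_equal(sdOfDeviations(reproducibility(y)), sdOfDeviations(res))
})

test_that("the coefficient increases monotonically with replicate noise", {
    coefAt <- function(s)
        avgDeviation(reproducibility(simulateExpression(
            300, 4, 2, replicateNoiseSd = s, seed = 77)))
    cs <- vapply(c(0, 0.2, 0.5), coefAt, numeric(1))
    expect_equal(cs[1], 0)
    expect_true(cs[1] < cs[2] && cs[2] < cs[3])
})

test_that("pooling and SD-convention options behave as documented", {
    x <- simulateExpression(40, 2, 3, replicateNoiseSd = 0.4, seed = 6)
    pooled <- reproducibility(x, pooling = "pooled")
    perStat <- reproducibility(x, pooling = "per-statistic")
    expect_equal(avgDeviation(pooled),
                 mean(c(pooled@meanDeviations, pooled@sdDeviations)))
    expect_equal(avgDeviation(perStat), mean(perStat@meanDeviations))
    expect_equal(perStat@perStatistic$sd$avg, mean(perStat@sdDeviations))

    # sample vs population SD of the deviations: (1,1,0,0) -> 0.5774 / 0.5
    micro <- reproducibility(microDataset(), sdType = "sample")
    expect_equal(sdOfDeviations(micro), sd(c(1, 1, 0, 0)), tolerance = 1e-12)
    microPop <- reproducibility(microDataset(), sdType = "population")
    expect_equal(sdOfDeviations(microPop), 0.5)
})

test_that("within-treatment deviations use the same folding on ratio means", {
    x <- makeDataset(cbind(c(10, 20, 30), c(20, 40, 60)), 1, 2)
    w <- withinTreatmentDeviation(x, "T1")
    tab <- as.data.frame(comparisons(w))
    expect_equal(sort(tab$M), c(0.5, 2))      # both ordered pairs
    expect_equal(tab$deviation, c(1, 1))      # folded identically
    expect_equal(avgDeviation(w), 1)

    expect_error(withinTreatmentDeviation(
        simulateExpression(10, 2, 1, seed = 1), "T1"), "< 2 replicates")
})

test_that("within-treatment deviation grows with technical noise", {
    at <- function(s) avgDeviation(withinTreatmentDeviation(
        simulateExpression(400, 1, 3, replicateNoiseSd = s, seed = 15),
        "T1"))
    v <- vapply(c(0.05, 0.2, 0.5), at, numeric(1))
    expect_true(all(v > 0))
    expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("listwise gene filtering drops genes missing anywhere", {
    m <- cbind(c(10, 0, 5), c(12, 3, 6), c(30, 4, NA), c(28, 5, 7))
    x <- makeDataset(m, 2, 2)
    pw <- buildRatioPopulations(x, geneFilter = "pairwise")
    lw <- buildRatioPopulations(x, geneFilter = "listwise")
    # listwise: only g1 survives everywhere
    expect_true(all(populations(lw)$n == 1L))
    # pairwise: populations not touching the bad cells keep more genes
    expect_true(any(populations(pw)$n > 1L))
})
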