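# brute-force oracles, written as literal enumerations independent of the
# package's implementation path

# enumerate every ratio population and every statistic ratio by explicit
# nested loops over the layout
oracleReproducibility <- function(mat, layout) {
    trts <- unique(layout$treatment)
    devsM <- c(); devsS <- c(); nPop <- 0L; skipped <- 0L
    colOf <- function(t, r)
        layout$sample[layout$treatment == t & layout$replicate == r]
    for (a in trts) for (b in trts) {
        if (a == b) next
        ra <- layout$replicate[layout$treatment == a]
        rb <- layout$replicate[layout$treatment == b]
        M <- matrix(NA_real_, length(ra), length(rb))
        S <- matrix(NA_real_, length(ra), length(rb))
        for (i in seq_along(ra)) for (j in seq_along(rb)) {
            xa <- mat[, colOf(a, ra[i])]
            xb <- mat[, colOf(b, rb[j])]
            keep <- !is.na(xa) & !is.na(xb) & xa > 0 & xb > 0
            rat <- xa[keep] / xb[keep]
            M[i, j] <- mean(rat)
            S[i, j] <- if (length(rat) >= 2) sd(rat) else NA_real_
            nPop <- nPop + 1L
        }
        if (length(rb) < 2) next
        for (i in seq_along(ra))
            for (j in 1:(length(rb) - 1)) for (k in (j + 1):length(rb)) {
                v <- M[i, j] / M[i, k]
                devsM <- c(devsM, if (v >= 1) v - 1 else 1 / v - 1)
                s1 <- S[i, j]; s2 <- S[i, k]
                if (is.na(s1) || is.na(s2) || s1 == 0 || s2 == 0) {
                    skipped <- skipped + 1L
                } else {
                    v <- s1 / s2
                    devsS <- c(devsS, if (v >= 1) v - 1 else 1 / v - 1)
                }
            }
    }
    pooled <- c(devsM, devsS)
    list(meanDeviations = devsM, sdDeviations = devsS,
         avgDeviation = mean(pooled),
         sdOfDeviations = if (length(pooled) >= 2) sd(pooled) else NA_real_,
         nPopulations = nPop,
         nComparisonsPerStat = length(devsM), skipped = skipped)
}

# test every observed fold change as candidate threshold
oracleFCThreshold <- function(fc, alpha) {
    best <- Inf
    for (t in sort(unique(fc)))
        if (sum(fc >= t) / length(fc) < alpha && t < best) best <- t
    best  # Inf when even the maximum is too frequent
}
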