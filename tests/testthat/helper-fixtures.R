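# in-code fixtures shared across test files

# tiny dataset with explicit values; columns named T<i>_R<k>
makeDataset <- function(values, nTreat, nRep, geneIds = NULL) {
    values <- as.matrix(values)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(values)))
    tl <- paste0("T", seq_len(nTreat)); rl <- paste0("R", seq_len(nRep))
    lay <- expand.grid(replicate = rl, treatment = tl,
                       stringsAsFactors = FALSE)[, 2:1]
    lay$sample <- paste0(lay$treatment, "_", lay$replicate)
    stopifnot(ncol(values) == nrow(lay))
    dimnames(values) <- list(geneIds, lay$sample)
    ExpressionDataset(values, lay)
}

# the 2-treatment / 2-replicate / 2-gene hand-enumerated case:
# T1 replicates identical; T2 replicate 1 doubled relative to replicate 2
microDataset <- function() {
    makeDataset(cbind(c(10, 20), c(10, 20), c(20, 40), c(10, 20)),
                nTreat = 2, nRep = 2)
}

# the printed worked example: equal transcript induction, ORF lengths in
# 1000-bp steps, decreasing observed protein fold changes
table2Fixture <- function() {
    data.frame(gene = paste0("G", 1:8), TF = 2,
               ORF = seq(1000, 8000, by = 1000),
               PF = c(10, 9, 8, 7, 6, 5, 4, 3))
}

writeMatrixFixture <- function(dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
    mat <- file.path(dir, "m.tsv")
    lay <- file.path(dir, "m.layout.tsv")
    writeLines(c("gene\ts1\ts2\ts3\ts4",
                 "g1\t10\t12\t30\t31",
                 "g2\t5\t6\t2\t2.5",
                 "g3\t100\t90\t80\t85"), mat)
    writeLines(c("sample\ttreatment\treplicate",
                 "s1\tT1\tR1", "s2\tT1\tR2",
                 "s3\tT2\tR1", "s4\tT2\tR2"), lay)
    list(matrix = mat, layout = lay)
}

randomDesign <- function(nTreat, nRep, nGenes) {
    makeDataset(matrix(exp(rnorm(nGenes * nTreat * nRep, log(50), 1)),
                       nGenes, nTreat * nRep),
                nTreat = nTreat, nRep = nRep)
}
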