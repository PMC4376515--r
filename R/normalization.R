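#' RPKM correction of read counts
#'
#' Reads per kilobase of exon model per million mapped reads:
#' \deqn{RPKM_{ij} = c_{ij} \cdot 10^9 / (N_j \cdot L_i)}
#' with \eqn{c_{ij}} the read count of gene i in sample j, \eqn{N_j} the
#' total mapped reads of sample j (column sums unless supplied) and
#' \eqn{L_i} the gene length in bp.
#'
#' @param x an \code{\link{ExpressionDataset}} of read counts.
#' @param lengths named gene-length vector (bp) covering all genes.
#' @param totals optional per-sample total mapped reads (named or in column
#'   order); defaults to the column sums.
#' @return an \code{ExpressionDataset} of RPKM values; the correction is
#'   recorded in the metadata.
#' @export
rpkm <- function(x, lengths, totals = NULL) {
    stopifnot(is(x, "ExpressionDataset"))
    m <- exprValues(x)
    missing <- setdiff(rownames(m), names(lengths))
    if (length(missing))
        stop("no length for gene(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
    L <- lengths[rownames(m)]
    if (is.null(totals)) totals <- colSums(m, na.rm = TRUE)
    if (!is.null(names(totals))) totals <- totals[colnames(m)]
    if (length(totals) != ncol(m)) stop("one total per sample required")
    if (any(totals <= 0)) stop("zero total reads in sample: ",
                               colnames(m)[which(totals <= 0)[1L]])
    out <- sweep(m, 2L, totals, "/") * 1e9 / L
    .replaceValues(x, out, record = list(method = "rpkm",
                                         totals = as.numeric(totals)))
}

#' Library-size (total read count) scaling
#'
#' Scales each sample so its column sum equals a common target (the mean
#' library size by default). This is the read-count-based correction: a
#' pure per-sample scale bias between replicates is removed entirely,
#' moving the inter-replicate regression slope toward 1 while leaving the
#' Pearson correlation unchanged.
#'
#' @param x an \code{\link{ExpressionDataset}}.
#' @param target \code{"mean-library"} (default) or an explicit numeric
#'   target sum.
#' @return scaled \code{ExpressionDataset}; per-sample scale factors are
#'   recorded in the metadata.
#' @export
totalCountScaling <- function(x, target = "mean-library") {
    stopifnot(is(x, "ExpressionDataset"))
    m <- exprValues(x)
    sums <- colSums(m, na.rm = TRUE)
    if (any(sums <= 0)) stop("zero column sum in sample: ",
                             colnames(m)[which(sums <= 0)[1L]])
    tgt <- if (identical(target, "mean-library")) mean(sums)
           else as.numeric(target)
    if (!is.finite(tgt) || tgt <= 0) stop("invalid target library size")
    factors <- tgt / sums
    out <- sweep(m, 2L, factors, "*")
    .replaceValues(x, out, record = list(method = "total-count",
                                         target = tgt,
                                         factors = stats::setNames(
                                             as.numeric(factors),
                                             colnames(m))))
}

#' Reference-gene-based inter-replicate scaling
#'
#' Within each treatment, the first replicate is the anchor; every other
#' replicate k is multiplied by the mean, over the reference genes, of
#' (value in the anchor replicate / value in replicate k). With a single
#' reference gene its inter-replicate variation is driven to zero exactly.
#' The anchor choice is arbitrary but recorded in the metadata so the
#' correction is reproducible.
#'
#' @param x an \code{\link{ExpressionDataset}}.
#' @param referenceGenes character vector of reference gene ids; each must
#'   be present with positive values in every sample of every treatment.
#' @return scaled \code{ExpressionDataset} with factors in the metadata.
#' @export
referenceGeneScaling <- function(x, referenceGenes) {
    stopifnot(is(x, "ExpressionDataset"))
    if (!length(referenceGenes)) stop("need >= 1 reference gene")
    m <- exprValues(x)
    absent <- setdiff(referenceGenes, rownames(m))
    if (length(absent))
        stop("reference gene absent from dataset: ", absent[1L])
    factors <- stats::setNames(rep(1, ncol(m)), colnames(m))
    for (t in treatments(x)) {
        reps <- replicatesOf(x, t)
        anchor <- .sampleName(x, t, reps[1L])
        for (k in reps[-1L]) {
            sk <- .sampleName(x, t, k)
            va <- m[referenceGenes, anchor]
            vk <- m[referenceGenes, sk]
            bad <- referenceGenes[is.na(va) | is.na(vk) | va <= 0 | vk <= 0]
            if (length(bad))
                stop("reference gene '", bad[1L],
                     "' is zero or missing in samples of treatment ", t)
            factors[sk] <- mean(va / vk)
        }
    }
    out <- sweep(m, 2L, factors, "*")
    .replaceValues(x, out, record = list(method = "reference-gene",
                                         referenceGenes = referenceGenes,
                                         anchor = "first replicate",
                                         factors = factors))
}

#' Quantile normalization
#'
#' Classical quantile normalization: each sample's values are replaced by
#' the across-sample mean of the order statistics at their rank, ties
#' resolved by rank average. All column distributions become identical as
#' multisets, and the operation is idempotent. Delegates to
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param x an \code{\link{ExpressionDataset}} with >= 2 samples.
#' @return quantile-normalized \code{ExpressionDataset}.
#' @export
quantileNormalize <- function(x) {
    stopifnot(is(x, "ExpressionDataset"))
    m <- exprValues(x)
    if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    .replaceValues(x, out, record = list(method = "quantile",
                                         ties = "rank-average"))
}

# new dataset with the same layout, values replaced, correction recorded
.replaceValues <- function(x, values, record) {
    md <- metadata(x)
    md$normalization <- c(md$normalization, list(record))
    out <- ExpressionDataset(values, sampleLayout(x), metadata = md)
    out
}
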