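#' Empirical inter-replicate fold-change distribution
#'
#' For each requested within-treatment replicate pair and each gene with
#' positive values in both replicates, the fold change
#' \eqn{FC = \max(x, y)/\min(x, y) \ge 1}; values from all pairs are pooled.
#' Under the assumption that extreme inter-replicate variation is random
#' rather than gene-specific, this distribution is the empirical null for
#' judging inter-treatment fold changes.
#'
#' @param x an \code{\link{ExpressionDataset}}.
#' @param pairs replicate pairs to use: \code{NULL} (default) for all
#'   within-treatment replicate pairs, or a data.frame with columns
#'   \code{treatment}, \code{replicate1}, \code{replicate2}.
#' @return numeric vector of pooled fold changes with attributes
#'   \code{pairs} (the pairs used) and \code{nGenes} (per-pair gene counts).
#' @export
interReplicateFC <- function(x, pairs = NULL) {
    stopifnot(is(x, "ExpressionDataset"))
    if (is.null(pairs)) {
        rows <- list(); idx <- 0L
        for (t in treatments(x)) {
            reps <- replicatesOf(x, t)
            if (length(reps) < 2L) next
            for (i in seq_len(length(reps) - 1L))
                for (j in seq((i + 1L), length(reps))) {
                    idx <- idx + 1L
                    rows[[idx]] <- data.frame(treatment = t,
                        replicate1 = reps[i], replicate2 = reps[j],
                        stringsAsFactors = FALSE)
                }
        }
        if (!idx) stop("no treatment with >= 2 replicates")
        pairs <- do.call(rbind, rows)
    }
    pairs <- as.data.frame(pairs)
    need <- c("treatment", "replicate1", "replicate2")
    if (!all(need %in% colnames(pairs)))
        stop("pairs must have columns: ", paste(need, collapse = ", "))
    fc <- list(); nGenes <- integer(nrow(pairs))
    for (q in seq_len(nrow(pairs))) {
        xa <- .sampleValues(x, pairs$treatment[q], pairs$replicate1[q])
        xb <- .sampleValues(x, pairs$treatment[q], pairs$replicate2[q])
        keep <- !is.na(xa) & !is.na(xb) & xa > 0 & xb > 0
        fc[[q]] <- pmax(xa[keep], xb[keep]) / pmin(xa[keep], xb[keep])
        nGenes[q] <- sum(keep)
    }
    out <- unlist(fc, use.names = FALSE)
    if (!length(out)) stop("no usable genes in the requested pairs")
    attr(out, "pairs") <- pairs
    attr(out, "nGenes") <- nGenes
    out
}

#' Fold-change threshold at a false-positive likelihood
#'
#' The threshold is the smallest observed fold change t such that the
#' empirical frequency of inter-replicate fold changes at or above t is
#' below \code{alpha}: a significant inter-treatment fold change above t
#' then has an inter-replicate occurrence likelihood lower than
#' \code{alpha}. Candidates are restricted to observed values (between
#' observed values the frequency is flat). If even the maximum observed
#' value occurs with frequency >= alpha (e.g. all fold changes identical),
#' the threshold is set just above the maximum and flagged
#' (\code{aboveMax}).
#'
#' @param foldChanges fold-change values (>= 1), e.g. from
#'   \code{\link{interReplicateFC}}.
#' @param alpha acceptable false-positive likelihood in (0, 1), typically
#'   0.05 or 0.01. A warning is given when fewer than 1/alpha values are
#'   supplied.
#' @param groupKey,groupLabel bookkeeping for grouped thresholds.
#' @return an \code{\link[=FCThresholdResult-class]{FCThresholdResult}}.
#' @examples
#' fc <- c(rep(1.1, 90), rep(2, 6), rep(4, 4))
#' threshold(fcThreshold(fc, 0.05))   # 4
#' threshold(fcThreshold(fc, 0.15))   # 2
#' @export
fcThreshold <- function(foldChanges, alpha = 0.05, groupKey = "none",
                        groupLabel = NA_character_) {
    fc <- as.numeric(foldChanges)
    if (!length(fc)) stop("empty fold-change distribution")
    if (any(is.na(fc)) || any(fc < 1))
        stop("fold changes must be >= 1 (max/min convention)")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (length(fc) < 1 / alpha)
        warning("fewer than 1/alpha (", ceiling(1 / alpha),
                ") fold-change values; threshold is unstable")
    n <- length(fc)
    cand <- sort(unique(fc))
    # frequency of FC >= t for each candidate t, largest t first
    ok <- vapply(cand, function(t) sum(fc >= t) / n < alpha, logical(1))
    if (any(ok)) {
        thr <- min(cand[ok])
        aboveMax <- FALSE
    } else {
        thr <- max(fc) * (1 + 1e-9)
        aboveMax <- TRUE
    }
    new("FCThresholdResult", alpha = alpha, foldChanges = fc,
        threshold = thr, aboveMax = aboveMax,
        nGenes = length(attr(foldChanges, "nGenes") %||% integer()),
        nValues = n,
        sourcePairs = DataFrame(attr(foldChanges, "pairs") %||%
            data.frame(treatment = character(), replicate1 = character(),
                       replicate2 = character())),
        groupKey = groupKey, groupLabel = groupLabel,
        lowN = length(fc) < 20L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter significant expression changes by the fold-change threshold
#'
#' Among genes flagged significant by an external differential-expression
#' procedure, those whose inter-treatment fold change (max/min convention)
#' is at or below the threshold show the same or lower change than is
#' expected between replicates, and are reported as sub-threshold
#' (unreliable); strictly larger fold changes pass.
#'
#' @param table data.frame with columns \code{gene}, \code{fc} (>= 1) and
#'   \code{significant} (logical).
#' @param threshold a numeric threshold or an \code{FCThresholdResult}.
#' @return list with \code{table} (input plus a \code{subThreshold} column,
#'   significant genes only), \code{nSignificant}, \code{nSubThreshold},
#'   \code{nPassing} and \code{fractionSubThreshold}.
#' @export
applyThreshold <- function(table, threshold) {
    if (is(threshold, "FCThresholdResult")) threshold <- threshold@threshold
    table <- as.data.frame(table)
    need <- c("gene", "fc", "significant")
    if (!all(need %in% colnames(table)))
        stop("table must have columns: ", paste(need, collapse = ", "))
    if (nrow(table) && any(table$fc < 1, na.rm = TRUE))
        stop("fc < 1 violates the max/min fold-change convention")
    sig <- table[table$significant %in% TRUE, , drop = FALSE]
    sig$subThreshold <- sig$fc <= threshold
    list(table = sig,
         nSignificant = nrow(sig),
         nSubThreshold = sum(sig$subThreshold),
         nPassing = sum(!sig$subThreshold),
         fractionSubThreshold = if (nrow(sig)) mean(sig$subThreshold)
                                else NA_real_)
}

#' Gene-group-specific fold-change thresholds
#'
#' When inter-replicate variation is biased toward particular gene groups
#' (short or low-abundance genes vary more in RNA-Seq), one global threshold
#' over-filters the stable groups and under-filters the noisy ones. This
#' computes \code{\link{fcThreshold}} independently within gene bins defined
#' by ORF/exon length or by mean expression across the replicates used.
#'
#' @param x an \code{\link{ExpressionDataset}}.
#' @param alpha false-positive likelihood.
#' @param groupBy \code{"length"} or \code{"abundance"}.
#' @param bins numeric break points (passed to \code{cut}; must cover the
#'   grouping value range).
#' @param lengths named gene-length vector, required for
#'   \code{groupBy = "length"}.
#' @param pairs replicate pairs, as in \code{\link{interReplicateFC}}.
#' @return named list of \code{FCThresholdResult} (one per non-empty bin);
#'   empty bins appear as \code{NULL}. Bins with < 20 genes are computed but
#'   flagged (\code{lowN}) with a warning.
#' @export
groupedThresholds <- function(x, alpha = 0.05,
                              groupBy = c("length", "abundance"),
                              bins, lengths = NULL, pairs = NULL) {
    groupBy <- match.arg(groupBy)
    stopifnot(is(x, "ExpressionDataset"))
    fcAll <- interReplicateFC(x, pairs)
    usedPairs <- attr(fcAll, "pairs")
    m <- exprValues(x)
    if (groupBy == "length") {
        if (is.null(lengths)) stop("lengths required for groupBy = 'length'")
        missing <- setdiff(rownames(m), names(lengths))
        if (length(missing))
            stop("no length for gene(s): ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        key <- lengths[rownames(m)]
    } else {
        cols <- unique(unlist(lapply(seq_len(nrow(usedPairs)), function(q)
            c(.sampleName(x, usedPairs$treatment[q], usedPairs$replicate1[q]),
              .sampleName(x, usedPairs$treatment[q],
                          usedPairs$replicate2[q])))))
        key <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
    }
    grp <- cut(key, breaks = bins, include.lowest = TRUE)
    if (any(is.na(grp)))
        stop("bins must cover the full range of the grouping value")
    out <- stats::setNames(vector("list", nlevels(grp)), levels(grp))
    for (lev in levels(grp)) {
        genes <- rownames(m)[grp == lev]
        fcGrp <- .geneFoldChanges(x, usedPairs, genes)
        if (!length(fcGrp)) next   # empty bin: NULL entry, flagged by absence
        if (length(unique(genes)) < 20L)
            warning("bin '", lev, "' has < 20 genes; threshold flagged")
        out[[lev]] <- fcThreshold(fcGrp, alpha, groupKey = groupBy,
                                  groupLabel = lev)
    }
    out
}

# pooled fold changes restricted to a gene subset
.geneFoldChanges <- function(x, pairs, genes) {
    fc <- list()
    for (q in seq_len(nrow(pairs))) {
        xa <- .sampleValues(x, pairs$treatment[q], pairs$replicate1[q])[genes]
        xb <- .sampleValues(x, pairs$treatment[q], pairs$replicate2[q])[genes]
        keep <- !is.na(xa) & !is.na(xb) & xa > 0 & xb > 0
        fc[[q]] <- pmax(xa[keep], xb[keep]) / pmin(xa[keep], xb[keep])
    }
    out <- unlist(fc, use.names = FALSE)
    if (is.null(out)) numeric() else out
}

#' Accessors for FCThresholdResult
#' @param x an \code{FCThresholdResult}.
#' @name FCThresholdResult-accessors
#' @aliases threshold alphaLevel foldChanges
NULL

#' @rdname FCThresholdResult-accessors
#' @export
setMethod("threshold", "FCThresholdResult", function(x) x@threshold)

#' @rdname FCThresholdResult-accessors
#' @export
setMethod("alphaLevel", "FCThresholdResult", function(x) x@alpha)

#' @rdname FCThresholdResult-accessors
#' @export
setMethod("foldChanges", "FCThresholdResult", function(x) x@foldChanges)

setMethod("show", "FCThresholdResult", function(object) {
    cat("FCThresholdResult: threshold > ",
        format(object@threshold, digits = 4), " at alpha = ", object@alpha,
        "\n  ", object@nValues, " pooled fold changes",
        if (object@aboveMax) "  [even max FC too frequent: flagged]",
        if (object@lowN) "  [n < 20: flagged]", "\n", sep = "")
    if (!is.na(object@groupLabel))
        cat("  group (", object@groupKey, "): ", object@groupLabel, "\n",
            sep = "")
    invisible(NULL)
})
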