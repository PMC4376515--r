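#' Read a delimited expression matrix with its sample layout
#'
#' The matrix file has gene ids in the first column and one header column per
#' sample. The layout maps every sample name to a (treatment, replicate)
#' pair; it can be given as a data.frame or as a sidecar delimited file with
#' columns \code{sample}, \code{treatment}, \code{replicate}. The delimiter
#' is auto-detected among tab, comma and semicolon unless given.
#'
#' Validation is strict: duplicate gene ids, samples missing from the layout
#' and non-numeric cells are hard errors (the error names the offending id or
#' cell). Rows containing a negative value are rejected (dropped with a
#' warning; ids recorded in the dataset metadata). \code{NA} cells are kept:
#' downstream operations exclude genes with missing values in the samples
#' they use and count them.
#'
#' @param path matrix file.
#' @param layout data.frame or path to a layout sidecar file.
#' @param delim field separator; \code{NULL} to auto-detect.
#' @return an \code{\link{ExpressionDataset}}.
#' @export
readExpressionMatrix <- function(path, layout, delim = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(delim)) delim <- .sniffDelim(path)
    raw <- utils::read.delim(path, sep = delim, header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             comment.char = "#")
    if (ncol(raw) < 2L) stop("matrix file needs gene ids plus >= 1 sample")
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate gene id: ", ids[duplicated(ids)][1L])
    samples <- colnames(raw)[-1L]
    vals <- matrix(NA_real_, nrow(raw), length(samples),
                   dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
        col <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num) & !is.na(col) &
                     !(trimws(col) %in% c("", "NA", "na", "NaN")))
        if (length(bad))
            stop("non-numeric cell at row ", bad[1L], " (gene ", ids[bad[1L]],
                 "), column '", samples[j], "': '", col[bad[1L]], "'")
        vals[, j] <- num
    }
    if (is.character(layout) && length(layout) == 1L)
        layout <- readLayout(layout)
    neg <- which(apply(vals < 0, 1L, any, na.rm = TRUE))
    rejected <- character()
    if (length(neg)) {
        rejected <- ids[neg]
        warning("rejected ", length(neg),
                " row(s) with negative values: ",
                paste(utils::head(rejected, 5L), collapse = ", "),
                if (length(rejected) > 5L) ", ..." else "")
        vals <- vals[-neg, , drop = FALSE]
    }
    ExpressionDataset(vals, layout,
        metadata = list(source = path, rejectedRows = rejected))
}

#' Read a sample layout sidecar file
#'
#' @param path delimited file with columns sample, treatment, replicate
#'   (header required).
#' @param delim separator; auto-detected when \code{NULL}.
#' @return data.frame with columns sample, treatment, replicate.
#' @export
readLayout <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(delim)) delim <- .sniffDelim(path)
    lay <- utils::read.delim(path, sep = delim, header = TRUE,
                             check.names = FALSE,
                             colClasses = "character", comment.char = "#")
    need <- c("sample", "treatment", "replicate")
    if (!all(need %in% colnames(lay)))
        stop("layout file must have columns: ", paste(need, collapse = ", "))
    lay[need]
}

#' Read a gene-length table
#'
#' Two-column delimited file: gene id, length in base pairs (ORF length or
#' total exon-model length). Lengths must be positive integers; duplicate
#' ids are an error.
#'
#' @param path file path.
#' @param delim separator; auto-detected when \code{NULL}.
#' @return named integer vector of lengths (names = gene ids).
#' @export
readLengthTable <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(delim)) delim <- .sniffDelim(path)
    tab <- utils::read.delim(path, sep = delim, header = TRUE,
                             check.names = FALSE,
                             colClasses = "character", comment.char = "#")
    if (ncol(tab) < 2L) stop("length table needs two columns (id, length)")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate gene id in length table: ", ids[duplicated(ids)][1L])
    len <- suppressWarnings(as.numeric(tab[[2L]]))
    if (any(is.na(len)))
        stop("non-numeric length for gene ", ids[which(is.na(len))[1L]])
    if (any(len < 1))
        stop("length <= 0 for gene ", ids[which(len < 1)[1L]])
    stats::setNames(as.integer(round(len)), ids)
}

#' Write an ExpressionDataset as matrix + layout files
#'
#' Values are written with 15 significant digits so that a read/write/read
#' round trip reproduces them.
#'
#' @param x an ExpressionDataset.
#' @param path matrix output path (TSV).
#' @param layoutPath layout sidecar path; default appends \code{.layout.tsv}.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path,
                                  layoutPath = paste0(path, ".layout.tsv")) {
    m <- exprValues(x)
    out <- data.frame(gene = rownames(m),
                      apply(m, 2L, .fmtNum),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out) <- c("gene", colnames(m))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sampleLayout(x), layoutPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---- writeReport methods ------------------------------------------------

.writeLines <- function(lines, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(lines, con)
}

.kv <- function(...) {
    v <- c(...)
    paste0(names(v), "\t", vapply(v, function(x)
        if (is.numeric(x)) .fmtNum(x) else as.character(x), character(1)))
}

#' @describeIn writeReport one row per statistic-ratio comparison plus a
#'   summary block of the two coefficients and all counts.
#' @export
setMethod("writeReport", "ReproducibilityResult",
    function(result, path, format = c("tsv", "text")) {
        format <- match.arg(format)
        cmp <- as.data.frame(result@comparisons)
        num <- vapply(cmp, is.numeric, logical(1))
        cmp[num] <- lapply(cmp[num], .fmtNum)
        head <- c(paste0("# mode\t", result@mode),
                  "# summary",
                  paste0("# ", .kv(c(
                      avg_deviation = result@avgDeviation,
                      sd_of_deviations = result@sdOfDeviations,
                      avg_deviation_mean_stat = result@perStatistic$mean$avg,
                      avg_deviation_sd_stat = result@perStatistic$sd$avg,
                      n_populations = result@nPopulations,
                      n_comparisons = result@nComparisons,
                      skipped = result@skipped,
                      pooling = result@pooling,
                      sd_type = result@sdType))))
        if (format == "text") {
            .writeLines(head, path)
        } else {
            body <- c(paste(colnames(cmp), collapse = "\t"),
                      do.call(paste, c(cmp, sep = "\t")))
            .writeLines(c(head, body), path)
        }
        invisible(path)
    })

#' @describeIn writeReport structured text containing alpha, the threshold
#'   and the source pairs; TSV adds the pooled fold-change values.
#' @export
setMethod("writeReport", "FCThresholdResult",
    function(result, path, format = c("tsv", "text")) {
        format <- match.arg(format)
        head <- paste0("# ", .kv(c(
            alpha = result@alpha, threshold = result@threshold,
            above_max = result@aboveMax, n_values = result@nValues,
            group_key = result@groupKey, group = result@groupLabel)))
        if (format == "text") {
            .writeLines(head, path)
        } else {
            .writeLines(c(head, "fold_change",
                          .fmtNum(result@foldChanges)), path)
        }
        invisible(path)
    })

#' @describeIn writeReport key-value summary of correlation, slope and the
#'   variation fraction.
#' @export
setMethod("writeReport", "ReplicateQCResult",
    function(result, path, format = c("tsv", "text")) {
        format <- match.arg(format)
        .writeLines(.kv(c(
            pearson_r = result@pearsonR, pearson_p = result@pearsonP,
            slope = result@slope, intercept = result@intercept,
            slope_deviation = result@slopeDeviation,
            n_genes_used = result@nGenesUsed,
            n_excluded = result@nExcluded,
            fraction_exceeding = result@fractionExceeding,
            cutoff = result@cutoff, log_base = result@logBase)), path)
        invisible(path)
    })

#' @describeIn writeReport the per-gene table (gene, TF, ORF, PF, CF, CPF)
#'   as TSV.
#' @export
setMethod("writeReport", "ProteinTranscriptTable",
    function(result, path, format = c("tsv", "text")) {
        df <- as.data.frame(result)
        df <- cbind(gene = rownames(df), df)
        num <- vapply(df, is.numeric, logical(1))
        df[num] <- lapply(df[num], .fmtNum)
        .writeLines(c(paste(colnames(df), collapse = "\t"),
                      do.call(paste, c(df, sep = "\t"))), path)
        invisible(path)
    })

#' @describeIn writeReport before/after Pearson and Spearman coefficients.
#' @export
setMethod("writeReport", "CorrelationShift",
    function(result, path, format = c("tsv", "text")) {
        .writeLines(.kv(c(
            r_before = result@rBefore, r_after = result@rAfter,
            rho_before = result@rhoBefore, rho_after = result@rhoAfter,
            p_before = result@pBefore, p_after = result@pAfter,
            n_genes = result@nGenes,
            undefined = if (length(result@undefined))
                paste(result@undefined, collapse = ",") else "none")), path)
        invisible(path)
    })

#' @describeIn writeReport any other type is an error.
#' @export
setMethod("writeReport", "ANY", function(result, path, format) {
    stop("writeReport: unsupported result type: ", class(result)[1L])
})
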