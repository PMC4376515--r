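#' Construct an ExpressionDataset
#'
#' @param values non-negative numeric matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample names).
#' @param layout data.frame with columns \code{sample}, \code{treatment},
#'   \code{replicate} covering every column of \code{values}.
#' @param metadata optional named list of provenance notes.
#'
#' @return an \code{ExpressionDataset}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' lay <- data.frame(sample = c("s1", "s2"),
#'                   treatment = "T1", replicate = c("R1", "R2"))
#' ExpressionDataset(m, lay)
#' @export
ExpressionDataset <- function(values, layout, metadata = list()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(colnames(values)))
        stop("'values' must have column (sample) names")
    if (is.null(rownames(values)))
        stop("'values' must have row (gene id) names")
    layout <- as.data.frame(layout)
    need <- c("sample", "treatment", "replicate")
    if (!all(need %in% colnames(layout)))
        stop("layout must have columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(values), layout$sample)
    if (length(missing))
        stop("sample(s) absent from layout: ", paste(missing, collapse = ", "))
    if (anyDuplicated(layout$sample))
        stop("duplicate sample in layout: ",
             layout$sample[duplicated(layout$sample)][1L])
    layout <- layout[match(colnames(values), layout$sample), , drop = FALSE]
    cd <- DataFrame(treatment = as.character(layout$treatment),
                    replicate = as.character(layout$replicate),
                    row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(exprs = values), colData = cd,
                               metadata = metadata)
    new("ExpressionDataset", se)
}

#' Accessors for ExpressionDataset
#'
#' \code{exprValues} returns the expression matrix; \code{sampleLayout} the
#' layout as a data.frame (sample, treatment, replicate); \code{treatments}
#' the treatment labels in order of first appearance; \code{replicatesOf}
#' the replicate labels of one treatment.
#'
#' @param x an \code{ExpressionDataset}.
#' @param treatment a treatment label.
#' @name ExpressionDataset-accessors
#' @aliases exprValues sampleLayout treatments replicatesOf
NULL

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("exprValues", "ExpressionDataset", function(x) assay(x, "exprs"))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("sampleLayout", "ExpressionDataset", function(x) {
    cd <- colData(x)
    data.frame(sample = rownames(cd), treatment = cd$treatment,
               replicate = cd$replicate, stringsAsFactors = FALSE)
})

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("treatments", "ExpressionDataset",
    function(x) unique(colData(x)$treatment))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("replicatesOf", "ExpressionDataset", function(x, treatment) {
    cd <- colData(x)
    reps <- cd$replicate[cd$treatment == treatment]
    if (!length(reps)) stop("unknown treatment: ", treatment)
    reps
})

# column name of one (treatment, replicate) sample
.sampleName <- function(x, treatment, replicate) {
    cd <- colData(x)
    hit <- which(cd$treatment == treatment & cd$replicate == replicate)
    if (length(hit) != 1L)
        stop("no unique sample for (", treatment, ", ", replicate, ")")
    rownames(cd)[hit]
}

# replicate column vector for one (treatment, replicate)
.sampleValues <- function(x, treatment, replicate) {
    exprValues(x)[, .sampleName(x, treatment, replicate)]
}

setMethod("show", "ExpressionDataset", function(object) {
    lay <- sampleLayout(object)
    cat("ExpressionDataset:", nrow(object), "genes x", ncol(object),
        "samples\n")
    for (t in unique(lay$treatment))
        cat("  ", t, ": replicates ",
            paste(lay$replicate[lay$treatment == t], collapse = ", "),
            "\n", sep = "")
    if (length(metadata(object)))
        cat("  metadata:", paste(names(metadata(object)), collapse = ", "),
            "\n")
    invisible(NULL)
})
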