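#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("sampleLayout", function(x) standardGeneric("sampleLayout"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("replicatesOf", function(x, treatment) standardGeneric("replicatesOf"))

#' @rdname ReproducibilityResult-accessors
#' @export
setGeneric("avgDeviation", function(x) standardGeneric("avgDeviation"))

#' @rdname ReproducibilityResult-accessors
#' @export
setGeneric("sdOfDeviations", function(x) standardGeneric("sdOfDeviations"))

#' @rdname ReproducibilityResult-accessors
#' @export
setGeneric("comparisons", function(x) standardGeneric("comparisons"))

#' @rdname RatioPopulationSet-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname FCThresholdResult-accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname FCThresholdResult-accessors
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))

#' @rdname FCThresholdResult-accessors
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' Write an analysis report to disk
#'
#' Serializes a result object deterministically, either as a TSV table
#' (\code{format = "tsv"}) or as a structured key-value text summary
#' (\code{format = "text"}). Numeric values keep at least 15 significant
#' digits so that reports round-trip.
#'
#' @param result a result object from this package.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"text"}.
#' @return invisibly, \code{path}.
#' @export
setGeneric("writeReport",
    function(result, path, format = c("tsv", "text"))
        standardGeneric("writeReport"))
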