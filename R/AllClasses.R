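#' ExpressionDataset: a gene-by-sample expression matrix with a replicate layout
#'
#' An \code{ExpressionDataset} is a \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one assay named \code{"exprs"} (non-negative expression values:
#' read counts, RPKM, intensities or t.p.m.) whose \code{colData} carries the
#' sample layout: a \code{treatment} and a \code{replicate} label per sample.
#' All statistics in this package key on \code{(treatment, replicate)}, never
#' on column order.
#'
#' Missing cells (\code{NA}) are tolerated in the container; every operation
#' excludes genes with missing (or, where ratios are taken, non-positive)
#' values in the samples it uses and reports the count excluded.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; use
#'   \code{\link{exprValues}}, \code{\link{sampleLayout}},
#'   \code{\link{treatments}} and \code{\link{replicatesOf}} to access it.
#'
#' @seealso \code{\link{ExpressionDataset}} (constructor),
#'   \code{\link{readExpressionMatrix}}, \code{\link{simulateExpression}}
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
    msg <- character()
    if (!("exprs" %in% assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    if (!all(c("treatment", "replicate") %in% colnames(cd))) {
        msg <- c(msg, "colData must have 'treatment' and 'replicate' columns")
    } else {
        key <- paste(cd$treatment, cd$replicate, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "replicate labels must be unique within a treatment")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if ("exprs" %in% assayNames(object)) {
        v <- assay(object, "exprs")
        if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, "expression values must be non-negative")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' Replicate-level quality control summary
#'
#' Holds the classical diagnostics for one replicate pair: Pearson r with its
#' two-tailed p-value, the ordinary least-squares slope and intercept of one
#' replicate against the other (on the requested scale), the slope deviation
#' from 1, and the fraction of genes whose inter-replicate variation
#' (fold ratio minus 1) exceeds a stated cutoff.
#'
#' @slot pearsonR,pearsonP Pearson correlation and two-tailed p-value.
#' @slot slope,intercept,slopeDeviation OLS fit of y on x; deviation is
#'   \code{abs(slope - 1)}.
#' @slot nGenesUsed,nExcluded genes used / excluded (zeros or NA).
#' @slot fractionExceeding,cutoff fraction of genes with variation above
#'   \code{cutoff} (linear scale, strict by default).
#' @slot logBase \code{"none"}, \code{"2"} or \code{"10"}: scale on which the
#'   correlation and regression were computed.
#' @slot throughOrigin logical; TRUE if slope was fit without intercept.
#' @exportClass ReplicateQCResult
setClass("ReplicateQCResult",
    representation(pearsonR = "numeric", pearsonP = "numeric",
        slope = "numeric", intercept = "numeric", slopeDeviation = "numeric",
        nGenesUsed = "integer", nExcluded = "integer",
        fractionExceeding = "numeric", cutoff = "numeric",
        logBase = "character", throughOrigin = "logical"))

#' Noise summary over a narrow expression interval
#'
#' Restricting the replicate scatter to a narrow window of the expression
#' axis exposes the fold-level disagreement that the full dynamic range
#' hides. Membership is decided on the per-gene mean of the two replicate
#' values; per-gene fold deviation is max/min of the pair.
#'
#' @slot interval numeric(2): \code{c(low, high)} on the expression axis.
#' @slot nPoints genes whose replicate mean falls inside the interval.
#' @slot maxFoldDeviation largest max/min ratio in the interval (>= 1);
#'   \code{NA} when \code{nPoints == 0}.
#' @slot quantileFoldDeviations named numeric of fold-deviation quantiles.
#' @exportClass IntervalNoiseSummary
setClass("IntervalNoiseSummary",
    representation(interval = "numeric", nPoints = "integer",
        maxFoldDeviation = "numeric", quantileFoldDeviations = "numeric"))

#' A set of inter-treatment (or inter-replicate) expression-ratio populations
#'
#' One population per ordered sample pair: the per-gene expression ratios
#' x[i, source]/x[i, target], with the population mean M and standard
#' deviation S. Both orders (a, b) and (b, a) are kept as separate
#' measurements to fix the asymmetry of ratios around 1.
#'
#' @slot populations a \code{DataFrame} with one row per population:
#'   sourceTreatment, sourceReplicate, targetTreatment, targetReplicate,
#'   n (genes used), nExcluded, M, S.
#' @slot ratios list of per-gene ratio vectors, parallel to the rows.
#' @slot mode \code{"between-treatments"} or \code{"between-replicates"}.
#' @slot sdType \code{"sample"} (n - 1) or \code{"population"} (n).
#' @slot geneFilter \code{"pairwise"} or \code{"listwise"} gene exclusion.
#' @exportClass RatioPopulationSet
setClass("RatioPopulationSet",
    representation(populations = "DFrame", ratios = "list",
        mode = "character", sdType = "character", geneFilter = "character"))

setValidity("RatioPopulationSet", function(object) {
    p <- object@populations
    if (length(object@ratios) != nrow(p))
        return("one ratio vector per population row required")
    if (any(p$M <= 0, na.rm = TRUE)) return("population means must be > 0")
    TRUE
})

#' Reproducibility coefficients from ratios of population statistics
#'
#' For every ordered treatment pair, the ratio populations that share the
#' same source replicate and differ only in the target replicate are compared
#' by taking the ratios of their means (and of their standard deviations).
#' Each statistic ratio v is folded into a deviation from 1
#' (\code{v - 1} if \code{v >= 1}, else \code{1/v - 1}). The average of all
#' deviations and their standard deviation are the reproducibility
#' coefficients: both are 0 under perfect reproducibility, and grow with
#' inter-replicate noise.
#'
#' @slot mode \code{"between-treatments"} or \code{"between-replicates"}.
#' @slot comparisons \code{DataFrame} with one row per statistic-ratio
#'   comparison (pair, source replicate, the two target replicates,
#'   statistic, ratio, deviation, skipped flag).
#' @slot meanDeviations,sdDeviations deviation lists for the mean- and
#'   SD-statistic ratios.
#' @slot avgDeviation,sdOfDeviations the two coefficients (on the deviation
#'   list selected by \code{pooling}).
#' @slot perStatistic list with the per-statistic breakdown
#'   (\code{$mean} and \code{$sd}, each with avg/sd/n).
#' @slot nPopulations,nComparisons,skipped counts; skipped counts SD
#'   comparisons whose ratio is undefined (either S zero or undefined).
#' @slot pooling \code{"pooled"} or \code{"per-statistic"}.
#' @slot sdType standard-deviation convention used throughout.
#' @exportClass ReproducibilityResult
setClass("ReproducibilityResult",
    representation(mode = "character", comparisons = "DFrame",
        meanDeviations = "numeric", sdDeviations = "numeric",
        avgDeviation = "numeric", sdOfDeviations = "numeric",
        perStatistic = "list", nPopulations = "integer",
        nComparisons = "integer", skipped = "integer",
        pooling = "character", sdType = "character"))

setValidity("ReproducibilityResult", function(object) {
    if (length(object@meanDeviations) &&
        any(object@meanDeviations < 0, na.rm = TRUE))
        return("deviations must be non-negative")
    if (length(object@sdDeviations) &&
        any(object@sdDeviations < 0, na.rm = TRUE))
        return("deviations must be non-negative")
    TRUE
})

#' Empirical inter-replicate fold-change threshold
#'
#' The smallest observed inter-replicate fold change t such that the
#' empirical frequency of fold changes >= t is below the chosen likelihood
#' alpha. Significant inter-treatment changes at or below t have an
#' inter-replicate occurrence likelihood of at least alpha and are deemed
#' unreliable.
#'
#' @slot alpha false-positive likelihood in (0, 1), typically 0.05 or 0.01.
#' @slot foldChanges pooled empirical fold changes (max/min convention, >= 1).
#' @slot threshold the derived threshold (>= 1).
#' @slot aboveMax TRUE when even the largest observed fold change occurs with
#'   frequency >= alpha; the threshold is then set just above the maximum.
#' @slot nGenes,nValues genes per pair and pooled value count.
#' @slot sourcePairs \code{DataFrame} of the within-treatment replicate pairs
#'   used (treatment, replicate1, replicate2).
#' @slot groupKey \code{"none"}, \code{"length"} or \code{"abundance"}.
#' @slot groupLabel bin label when grouped, otherwise \code{NA}.
#' @slot lowN TRUE when the group held fewer than 20 genes.
#' @exportClass FCThresholdResult
setClass("FCThresholdResult",
    representation(alpha = "numeric", foldChanges = "numeric",
        threshold = "numeric", aboveMax = "logical", nGenes = "integer",
        nValues = "integer", sourcePairs = "DFrame", groupKey = "character",
        groupLabel = "character", lowN = "logical"))

setValidity("FCThresholdResult", function(object) {
    if (length(object@foldChanges) && any(object@foldChanges < 1))
        return("fold changes must be >= 1 (max/min convention)")
    if (length(object@foldChanges)) {
        frac <- mean(object@foldChanges >= object@threshold)
        if (frac >= object@alpha)
            return("empirical P(FC >= threshold) must be < alpha")
    }
    TRUE
})

#' Per-gene transcript/protein table with ORF-length correction columns
#'
#' A \code{DataFrame} with one row per gene and columns \code{TF} (transcript
#' fold change or quantity), \code{PF} (observed protein fold change or
#' quantity), \code{ORF} (coding-sequence length, bp) and, after
#' \code{\link{correctProtein}}, \code{CF} (correction factor, ORF length
#' divided by the shortest ORF length in the table) and \code{CPF}
#' (corrected protein value, PF * CF). Gene ids are the rownames.
#'
#' @exportClass ProteinTranscriptTable
setClass("ProteinTranscriptTable", contains = "DFrame")

setValidity("ProteinTranscriptTable", function(object) {
    msg <- character()
    need <- c("TF", "PF", "ORF")
    if (!all(need %in% colnames(object)))
        return(paste("columns required:", paste(need, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (any(object$TF <= 0, na.rm = TRUE) || any(object$PF <= 0, na.rm = TRUE))
        msg <- c(msg, "TF and PF must be positive")
    if (any(object$ORF < 1, na.rm = TRUE))
        msg <- c(msg, "ORF lengths must be >= 1")
    if ("CF" %in% colnames(object) && length(object$CF) &&
        abs(min(object$CF) - 1) > 1e-12)
        msg <- c(msg, "min CF must equal 1 (shortest ORF)")
    if (length(msg)) msg else TRUE
})

#' Correlation shift after ORF-length-based protein correction
#'
#' Pearson and Spearman correlations of transcript versus protein values,
#' computed twice: on the observed protein values and on the length-corrected
#' values (protein * CF). A coefficient that is undefined (a constant input
#' vector) is reported as NA and named in \code{undefined}, never as 0.
#'
#' @slot rBefore,rAfter,rhoBefore,rhoAfter the four coefficients.
#' @slot pBefore,pAfter two-tailed p-values for the Pearson coefficients.
#' @slot nGenes genes used.
#' @slot table per-gene \code{DataFrame} (transcript, protein, ORF, CF,
#'   corrected protein).
#' @slot undefined names of coefficients that were undefined.
#' @exportClass CorrelationShift
setClass("CorrelationShift",
    representation(rBefore = "numeric", rAfter = "numeric",
        rhoBefore = "numeric", rhoAfter = "numeric",
        pBefore = "numeric", pAfter = "numeric", nGenes = "integer",
        table = "DFrame", undefined = "character"))
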