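#' Build the inter-treatment expression-ratio populations
#'
#' Step one of the ratio-statistics reproducibility assay. For every ordered
#' pair of treatments (a, b), a != b, and every combination of a replicate
#' of a with a replicate of b, the per-gene ratios
#' \eqn{x_{i,a,r} / x_{i,b,s}} form one population, summarized by its mean M
#' and standard deviation S. Both orders (a, b) and (b, a) are built as
#' separate measurements to fix the asymmetry of ratios around 1 (a
#' logarithmic transform is deliberately not used: it compresses the
#' differences the assay is meant to expose). For n treatments with
#' \eqn{r_a} replicates each, the number of populations is
#' \eqn{\sum_{a \ne b} r_a r_b} — 48 for a 4-treatment, 2-replicate design.
#'
#' Genes with a zero or missing value in either sample are excluded per
#' population (\code{geneFilter = "pairwise"}, the default) or genes not
#' positive in every sample of the dataset are excluded everywhere
#' (\code{"listwise"}).
#'
#' @param x an \code{\link{ExpressionDataset}} with >= 2 treatments.
#' @param sdType standard-deviation convention for S: \code{"sample"}
#'   (n - 1 denominator, default) or \code{"population"}.
#' @param geneFilter \code{"pairwise"} or \code{"listwise"}.
#' @return a \code{\link[=RatioPopulationSet-class]{RatioPopulationSet}}.
#' @seealso \code{\link{statisticRatioDeviations}},
#'   \code{\link{reproducibility}}
#' @export
buildRatioPopulations <- function(x, sdType = c("sample", "population"),
                                  geneFilter = c("pairwise", "listwise")) {
    sdType <- match.arg(sdType)
    geneFilter <- match.arg(geneFilter)
    stopifnot(is(x, "ExpressionDataset"))
    trts <- treatments(x)
    if (length(trts) < 2L)
        stop("between-treatment analysis needs >= 2 treatments")
    for (t in trts)
        if (length(replicatesOf(x, t)) < 2L)
            warning("treatment '", t, "' has < 2 replicates; its pairs are ",
                    "still built but contribute no replicate substitution")
    m <- exprValues(x)
    globalKeep <- if (geneFilter == "listwise")
        apply(!is.na(m) & m > 0, 1L, all) else rep(TRUE, nrow(m))
    rows <- list(); ratios <- list(); idx <- 0L
    for (a in trts) for (b in trts) {
        if (a == b) next
        for (r in replicatesOf(x, a)) for (s in replicatesOf(x, b)) {
            xa <- .sampleValues(x, a, r)
            xb <- .sampleValues(x, b, s)
            keep <- globalKeep & !is.na(xa) & !is.na(xb) & xa > 0 & xb > 0
            rat <- xa[keep] / xb[keep]
            idx <- idx + 1L
            ratios[[idx]] <- rat
            rows[[idx]] <- data.frame(
                sourceTreatment = a, sourceReplicate = r,
                targetTreatment = b, targetReplicate = s,
                n = length(rat), nExcluded = sum(!keep),
                M = mean(rat),
                S = if (length(rat)) .sdOf(rat, sdType) else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    new("RatioPopulationSet",
        populations = DataFrame(do.call(rbind, rows)),
        ratios = ratios, mode = "between-treatments",
        sdType = sdType, geneFilter = geneFilter)
}

#' Ratios of population statistics across replicate substitutions
#'
#' Step two of the assay. Within each ordered treatment pair (a, b) and for
#' each fixed source replicate r of a, the populations that differ only in
#' the target replicate of b are compared: for every unordered pair
#' \{s, s'\} of b's replicates, the statistic ratios M(r, s)/M(r, s') and
#' S(r, s)/S(r, s') are formed. Under perfect reproducibility every such
#' ratio is 1; each ratio v is folded into a deviation
#' \eqn{d = v - 1} if \eqn{v \ge 1}, else \eqn{1/v - 1}, so that v and 1/v
#' deviate equally. Comparisons per statistic number
#' \eqn{\sum_{a \ne b} r_a \binom{r_b}{2}} — 24 for the 4 x 2 design.
#'
#' SD comparisons in which either S is zero or undefined (single-gene
#' population) are skipped and counted, with a warning when exactly one of
#' the two is zero (the ratio would be 0 or infinite).
#'
#' @param pops a \code{RatioPopulationSet} from
#'   \code{\link{buildRatioPopulations}}.
#' @return a \code{\link[=ReproducibilityResult-class]{ReproducibilityResult}}
#'   with the comparison table and deviation lists; coefficients are filled
#'   by \code{\link{reproducibilityCoefficients}}.
#' @export
statisticRatioDeviations <- function(pops) {
    stopifnot(is(pops, "RatioPopulationSet"))
    p <- as.data.frame(pops@populations)
    rows <- list(); idx <- 0L; skipped <- 0L; oneZero <- 0L
    pairs <- unique(p[c("sourceTreatment", "targetTreatment")])
    for (q in seq_len(nrow(pairs))) {
        a <- pairs$sourceTreatment[q]; b <- pairs$targetTreatment[q]
        sub <- p[p$sourceTreatment == a & p$targetTreatment == b, ]
        tReps <- unique(sub$targetReplicate)
        if (length(tReps) < 2L) next
        for (r in unique(sub$sourceReplicate)) {
            for (i in seq_len(length(tReps) - 1L))
                for (j in seq((i + 1L), length(tReps))) {
                    s1 <- tReps[i]; s2 <- tReps[j]
                    p1 <- sub[sub$sourceReplicate == r &
                              sub$targetReplicate == s1, ]
                    p2 <- sub[sub$sourceReplicate == r &
                              sub$targetReplicate == s2, ]
                    for (stat in c("M", "S")) {
                        v1 <- p1[[stat]]; v2 <- p2[[stat]]
                        skip <- stat == "S" &&
                            (is.na(v1) || is.na(v2) || v1 == 0 || v2 == 0)
                        if (skip) {
                            skipped <- skipped + 1L
                            if (!is.na(v1) && !is.na(v2) &&
                                xor(v1 == 0, v2 == 0))
                                oneZero <- oneZero + 1L
                            ratio <- NA_real_; dev <- NA_real_
                        } else {
                            ratio <- v1 / v2
                            dev <- .foldDeviation(ratio)
                        }
                        idx <- idx + 1L
                        rows[[idx]] <- data.frame(
                            sourceTreatment = a, targetTreatment = b,
                            sourceReplicate = r, targetReplicate1 = s1,
                            targetReplicate2 = s2,
                            statistic = if (stat == "M") "mean" else "sd",
                            ratio = ratio, deviation = dev,
                            skipped = skip, stringsAsFactors = FALSE)
                    }
                }
        }
    }
    if (oneZero > 0L)
        warning(oneZero, " SD comparison(s) skipped with exactly one zero ",
                "standard deviation (ratio undefined/infinite)")
    cmp <- if (idx) DataFrame(do.call(rbind, rows)) else
        DataFrame(sourceTreatment = character(), targetTreatment = character(),
                  sourceReplicate = character(), targetReplicate1 = character(),
                  targetReplicate2 = character(), statistic = character(),
                  ratio = numeric(), deviation = numeric(),
                  skipped = logical())
    meanDev <- cmp$deviation[cmp$statistic == "mean" & !cmp$skipped]
    sdDev <- cmp$deviation[cmp$statistic == "sd" & !cmp$skipped]
    new("ReproducibilityResult", mode = pops@mode, comparisons = cmp,
        meanDeviations = as.numeric(meanDev), sdDeviations = as.numeric(sdDev),
        avgDeviation = NA_real_, sdOfDeviations = NA_real_,
        perStatistic = list(),
        nPopulations = nrow(pops@populations),
        nComparisons = as.integer(sum(cmp$statistic == "mean")),
        skipped = skipped, pooling = NA_character_, sdType = pops@sdType)
}

#' Reproducibility coefficients from the deviation lists
#'
#' The average of the statistic-ratio deviations and the standard deviation
#' of those deviations are the two reproducibility coefficients: both are 0
#' under perfect reproducibility, and larger values mean lower
#' reproducibility. The second coefficient indicates how constant the
#' reproducibility is across treatments. Mean- and SD-statistic deviations
#' are pooled into a single pair of coefficients by default; a per-statistic
#' breakdown is always included.
#'
#' Because the coefficients are data-dependent descriptive statistics, they
#' should be compared between analysis pipelines applied to the same
#' experiment (e.g. uncorrected vs normalized data), not across different
#' experiments.
#'
#' @param result a partial \code{ReproducibilityResult} from
#'   \code{\link{statisticRatioDeviations}}.
#' @param pooling \code{"pooled"} (default) or \code{"per-statistic"} (the
#'   headline coefficients are then from the mean-statistic deviations).
#' @param sdType convention for the SD of the deviations: \code{"sample"}
#'   (default) or \code{"population"}.
#' @return the completed \code{ReproducibilityResult}.
#' @export
reproducibilityCoefficients <- function(result,
                                        pooling = c("pooled",
                                                    "per-statistic"),
                                        sdType = c("sample", "population")) {
    pooling <- match.arg(pooling)
    sdType <- match.arg(sdType)
    stopifnot(is(result, "ReproducibilityResult"))
    md <- result@meanDeviations; sdv <- result@sdDeviations
    if (!length(md) && !length(sdv))
        stop("all comparisons skipped: no deviations to average")
    per <- list(
        mean = list(avg = if (length(md)) mean(md) else NA_real_,
                    sd = if (length(md)) .sdOf(md, sdType) else NA_real_,
                    n = length(md)),
        sd = list(avg = if (length(sdv)) mean(sdv) else NA_real_,
                  sd = if (length(sdv)) .sdOf(sdv, sdType) else NA_real_,
                  n = length(sdv)))
    pool <- if (pooling == "pooled") c(md, sdv) else md
    result@avgDeviation <- mean(pool)
    result@sdOfDeviations <- .sdOf(pool, sdType)
    result@perStatistic <- per
    result@pooling <- pooling
    result@sdType <- sdType
    result
}

#' One-call reproducibility assay on a dataset
#'
#' Convenience wrapper: builds the ratio populations, forms the statistic
#' ratios across replicate substitutions, and returns the completed
#' coefficients.
#'
#' @inheritParams buildRatioPopulations
#' @inheritParams reproducibilityCoefficients
#' @return a \code{\link[=ReproducibilityResult-class]{ReproducibilityResult}}.
#' @examples
#' x <- simulateExpression(100, 2, 2, replicateNoiseSd = 0.3, seed = 7)
#' reproducibility(x)
#' @export
reproducibility <- function(x, pooling = c("pooled", "per-statistic"),
                            sdType = c("sample", "population"),
                            geneFilter = c("pairwise", "listwise")) {
    sdType <- match.arg(sdType)
    pops <- buildRatioPopulations(x, sdType = sdType,
                                  geneFilter = match.arg(geneFilter))
    reproducibilityCoefficients(statisticRatioDeviations(pops),
                                pooling = match.arg(pooling),
                                sdType = sdType)
}

#' Within-treatment (inter-replicate) reproducibility deviation
#'
#' The same deviation idea applied between the replicates of one treatment:
#' for every ordered replicate pair (k, l), k != l, the population of
#' gene-wise ratios \eqn{x_{i,k} / x_{i,l}} has mean M and standard
#' deviation S, expected to be 1 and 0 under perfect reproducibility. The
#' deviation of each M from 1 is \eqn{\max(M, 1/M) - 1}; the coefficient is
#' the average over all ordered pairs, and each population's S is reported
#' alongside. Reliable measures need several replicates; with two
#' replicates the two ordered pairs give equal deviations by symmetry.
#'
#' @param x an \code{\link{ExpressionDataset}}.
#' @param treatment treatment label (>= 2 replicates).
#' @param sdType standard-deviation convention for S.
#' @return a \code{ReproducibilityResult} with
#'   \code{mode = "between-replicates"}; the comparison table holds one row
#'   per ordered replicate pair with its M, deviation and population S.
#' @export
withinTreatmentDeviation <- function(x, treatment,
                                     sdType = c("sample", "population")) {
    sdType <- match.arg(sdType)
    stopifnot(is(x, "ExpressionDataset"))
    reps <- replicatesOf(x, treatment)
    if (length(reps) < 2L)
        stop("treatment '", treatment, "' has < 2 replicates")
    rows <- list(); idx <- 0L
    for (k in reps) for (l in reps) {
        if (k == l) next
        xa <- .sampleValues(x, treatment, k)
        xb <- .sampleValues(x, treatment, l)
        keep <- !is.na(xa) & !is.na(xb) & xa > 0 & xb > 0
        rat <- xa[keep] / xb[keep]
        if (!length(rat))
            stop("no genes positive in both replicates (", k, ", ", l, ")")
        M <- mean(rat)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
            treatment = treatment, replicate1 = k, replicate2 = l,
            n = length(rat), nExcluded = sum(!keep), M = M,
            S = .sdOf(rat, sdType), deviation = .foldDeviation(M),
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    devs <- tab$deviation
    new("ReproducibilityResult", mode = "between-replicates",
        comparisons = DataFrame(tab), meanDeviations = devs,
        sdDeviations = numeric(),
        avgDeviation = mean(devs), sdOfDeviations = .sdOf(devs, sdType),
        perStatistic = list(mean = list(avg = mean(devs),
                                        sd = .sdOf(devs, sdType),
                                        n = length(devs))),
        nPopulations = as.integer(nrow(tab)),
        nComparisons = as.integer(nrow(tab)), skipped = 0L,
        pooling = "per-statistic", sdType = sdType)
}

## accessors / show --------------------------------------------------------

#' Accessors for RatioPopulationSet
#' @param x a \code{RatioPopulationSet}.
#' @name RatioPopulationSet-accessors
#' @aliases populations
NULL

#' @rdname RatioPopulationSet-accessors
#' @export
setMethod("populations", "RatioPopulationSet", function(x) x@populations)

#' Accessors for ReproducibilityResult
#' @param x a \code{ReproducibilityResult}.
#' @name ReproducibilityResult-accessors
#' @aliases avgDeviation sdOfDeviations comparisons
NULL

#' @rdname ReproducibilityResult-accessors
#' @export
setMethod("avgDeviation", "ReproducibilityResult", function(x)
    x@avgDeviation)

#' @rdname ReproducibilityResult-accessors
#' @export
setMethod("sdOfDeviations", "ReproducibilityResult", function(x)
    x@sdOfDeviations)

#' @rdname ReproducibilityResult-accessors
#' @export
setMethod("comparisons", "ReproducibilityResult", function(x) x@comparisons)

setMethod("show", "RatioPopulationSet", function(object) {
    cat("RatioPopulationSet (", object@mode, "): ",
        nrow(object@populations), " populations, sd = ", object@sdType,
        ", gene filter = ", object@geneFilter, "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "ReproducibilityResult", function(object) {
    cat("ReproducibilityResult (", object@mode, ")\n", sep = "")
    if (!is.na(object@avgDeviation))
        cat("  average deviation     = ",
            format(object@avgDeviation, digits = 4), " (",
            format(100 * object@avgDeviation, digits = 4), "%)\n",
            "  sd of the deviations  = ",
            format(object@sdOfDeviations, digits = 4), " (",
            format(100 * object@sdOfDeviations, digits = 4), "%)\n",
            "  pooling = ", object@pooling, ", sd type = ", object@sdType,
            "\n", sep = "")
    cat("  populations = ", object@nPopulations,
        ", comparisons per statistic = ", object@nComparisons,
        ", skipped = ", object@skipped, "\n", sep = "")
    invisible(NULL)
})
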