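#' Per-gene inter-replicate variation
#'
#' Variation of gene i between two replicate measurements x and y is the
#' fold ratio minus one: \eqn{\max(x_i, y_i)/\min(x_i, y_i) - 1}. It is
#' symmetric in the two replicates and invariant to a common positive
#' scaling of both. "Variation higher than 50\%" means the larger value
#' exceeds 1.5 times the smaller. Genes with a zero or missing value in
#' either replicate are excluded and counted.
#'
#' @param x,y replicate value vectors of equal length (named or not).
#' @return numeric vector of variations (>= 0) for the genes used, with
#'   attributes \code{nUsed} and \code{nExcluded}.
#' @examples
#' interReplicateVariation(c(7, 10, 10), c(7, 15, 4))  # 0, 0.5, 1.5
#' @export
interReplicateVariation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- !is.na(x) & !is.na(y) & x > 0 & y > 0
    if (!any(keep)) stop("no genes with positive values in both replicates")
    v <- pmax(x[keep], y[keep]) / pmin(x[keep], y[keep]) - 1
    attr(v, "nUsed") <- sum(keep)
    attr(v, "nExcluded") <- sum(!keep)
    v
}

#' Fraction of genes exceeding a variation cutoff
#'
#' @param variations per-gene variation values (from
#'   \code{\link{interReplicateVariation}}).
#' @param cutoff variation cutoff (>= 0); 0.5 corresponds to "50\%
#'   inter-replicate variation".
#' @param inclusive if TRUE count \code{variation >= cutoff} ("50\% or
#'   higher"); default is strict \code{>} (">50\%").
#' @return fraction in [0, 1] over the genes supplied.
#' @export
fractionExceeding <- function(variations, cutoff = 0.5, inclusive = FALSE) {
    if (!length(variations)) stop("empty variation vector")
    if (cutoff < 0) stop("cutoff must be >= 0")
    if (inclusive) mean(variations >= cutoff) else mean(variations > cutoff)
}

#' Inter-replicate correlation and regression diagnostics
#'
#' Fits the ordinary least-squares line of y on x (optionally through the
#' origin) and computes the Pearson correlation with its two-tailed p-value,
#' on the linear, log2 or log10 scale. The slope is reported together with
#' its absolute deviation from 1: a slope far from 1 flags a systematic
#' inter-replicate bias that the correlation coefficient alone cannot
#' detect, because Pearson r is invariant to scaling one replicate by a
#' positive constant while the slope is not. Note that the log-scale slope
#' is a different quantity from the linear-scale slope (a pure scaling
#' y = c x gives linear slope c but log slope 1 with intercept log c), so
#' log-scale slopes understate multiplicative bias.
#'
#' When a log base is given, genes with a zero in either replicate are
#' excluded (and counted) unless a positive \code{pseudocount} is supplied.
#'
#' @param x,y replicate value vectors.
#' @param logBase \code{"none"} (default), \code{"2"} or \code{"10"}.
#' @param throughOrigin fit the slope without an intercept.
#' @param pseudocount added to both replicates before log transform (0 =
#'   none; zeros are then excluded).
#' @param cutoff variation cutoff for the reported
#'   \code{fractionExceeding} (computed on the linear scale).
#' @param inclusive boundary convention for the fraction (see
#'   \code{\link{fractionExceeding}}).
#' @return a \code{\link[=ReplicateQCResult-class]{ReplicateQCResult}}.
#' @examples
#' x <- c(1, 2, 3, 4); replicateRegression(x, 2 * x)  # slope 2, r 1
#' @export
replicateRegression <- function(x, y, logBase = c("none", "2", "10"),
                                throughOrigin = FALSE, pseudocount = 0,
                                cutoff = 0.5, inclusive = FALSE) {
    logBase <- match.arg(as.character(logBase), c("none", "2", "10"))
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- !is.na(x) & !is.na(y)
    xs <- x[keep]; ys <- y[keep]
    if (logBase != "none") {
        if (pseudocount > 0) { xs <- xs + pseudocount; ys <- ys + pseudocount }
        pos <- xs > 0 & ys > 0
        xs <- xs[pos]; ys <- ys[pos]
        base <- as.numeric(logBase)
        xt <- log(xs, base); yt <- log(ys, base)
    } else {
        xt <- xs; yt <- ys
    }
    nUsed <- length(xt)
    if (nUsed < 3L) stop("need >= 3 genes after exclusion, got ", nUsed)
    if (stats::var(xt) == 0) stop("zero variance in x: slope undefined")
    fit <- if (throughOrigin) stats::lm(yt ~ xt + 0) else stats::lm(yt ~ xt)
    cf <- stats::coef(fit)
    slope <- unname(cf[["xt"]])
    intercept <- if (throughOrigin) 0 else unname(cf[["(Intercept)"]])
    ct <- stats::cor.test(xt, yt, method = "pearson",
                          alternative = "two.sided")
    varFrac <- tryCatch(
        fractionExceeding(interReplicateVariation(x, y), cutoff, inclusive),
        error = function(e) NA_real_)
    new("ReplicateQCResult", pearsonR = unname(ct$estimate),
        pearsonP = ct$p.value, slope = slope, intercept = intercept,
        slopeDeviation = abs(slope - 1), nGenesUsed = as.integer(nUsed),
        nExcluded = as.integer(length(x) - nUsed),
        fractionExceeding = varFrac, cutoff = cutoff, logBase = logBase,
        throughOrigin = throughOrigin)
}

#' Noise summary over a narrow interval of the expression range
#'
#' Genes whose replicate mean \code{(x + y)/2} falls inside
#' \code{[low, high]} are collected and their fold deviations
#' \code{max/min} summarized by the maximum and the requested quantiles.
#' An interval outside the data range yields an empty summary
#' (\code{nPoints = 0}), not an error.
#'
#' @param x,y replicate value vectors.
#' @param interval numeric(2): \code{c(low, high)}, low < high.
#' @param probs quantiles of the fold deviations to report.
#' @return an \code{\link[=IntervalNoiseSummary-class]{IntervalNoiseSummary}}.
#' @export
narrowIntervalSummary <- function(x, y, interval,
                                  probs = c(0.5, 0.9, 0.95)) {
    if (length(interval) != 2L || interval[1L] >= interval[2L])
        stop("interval must be c(low, high) with low < high")
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- !is.na(x) & !is.na(y) & x > 0 & y > 0
    xs <- x[keep]; ys <- y[keep]
    mid <- (xs + ys) / 2
    inside <- mid >= interval[1L] & mid <= interval[2L]
    if (!any(inside))
        return(new("IntervalNoiseSummary", interval = as.numeric(interval),
                   nPoints = 0L, maxFoldDeviation = NA_real_,
                   quantileFoldDeviations =
                       stats::setNames(rep(NA_real_, length(probs)),
                                       paste0("q", probs))))
    fd <- pmax(xs[inside], ys[inside]) / pmin(xs[inside], ys[inside])
    new("IntervalNoiseSummary", interval = as.numeric(interval),
        nPoints = sum(inside), maxFoldDeviation = max(fd),
        quantileFoldDeviations =
            stats::setNames(stats::quantile(fd, probs, names = FALSE),
                            paste0("q", probs)))
}

setMethod("show", "ReplicateQCResult", function(object) {
    cat("ReplicateQCResult (log base ", object@logBase, ")\n",
        "  Pearson r = ", format(object@pearsonR, digits = 4),
        " (two-tailed P = ", format(object@pearsonP, digits = 3), ")\n",
        "  slope = ", format(object@slope, digits = 4),
        " (deviation from 1: ", format(object@slopeDeviation, digits = 4),
        "), intercept = ", format(object@intercept, digits = 4), "\n",
        "  genes used = ", object@nGenesUsed,
        " (excluded ", object@nExcluded, ")\n",
        "  fraction with variation > ", object@cutoff, " = ",
        format(object@fractionExceeding, digits = 4), "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "IntervalNoiseSummary", function(object) {
    cat("IntervalNoiseSummary [", object@interval[1L], ", ",
        object@interval[2L], "]: n = ", object@nPoints, sep = "")
    if (object@nPoints > 0)
        cat(", max fold deviation = ",
            format(object@maxFoldDeviation, digits = 4), sep = "")
    cat("\n")
    invisible(NULL)
})
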