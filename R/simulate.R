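#' Simulate a replicated expression dataset
#'
#' Generates a gene-by-sample matrix under a multiplicative model: the value
#' of gene i in replicate k of treatment t is
#' \deqn{x_{itk} = b_i \cdot e_{it} \cdot \epsilon_{itk}}
#' where the baseline \eqn{b_i} is log-normal, \eqn{e_{it}} is a per-gene,
#' per-treatment fold-change effect, and the replicate noise
#' \eqn{\epsilon_{itk}} is log-normal with log-standard-deviation
#' \code{replicateNoiseSd}. With \code{replicateNoiseSd = 0} the replicates
#' of a treatment are exactly identical, so every downstream reproducibility
#' deviation is exactly 0. The noise is multiplicative (symmetric on the log
#' scale) because all reproducibility statistics in this package are
#' ratio-based.
#'
#' A fixed \code{seed} gives a bit-identical dataset; the caller's random
#' number generator state is left untouched.
#'
#' @param nGenes number of genes.
#' @param treatments number of treatments (>= 2) or a character vector of
#'   treatment labels.
#' @param replicates replicates per treatment (>= 2 for downstream
#'   reproducibility analyses) or a character vector of replicate labels.
#' @param logMean,logSd log-scale mean and sd of the baseline distribution.
#' @param effects per-treatment fold-change effects: \code{NULL} (all 1),
#'   a numeric vector of length n (one fold per treatment, all genes), or a
#'   genes-by-treatments matrix.
#' @param replicateNoiseSd log-scale sd of the multiplicative replicate
#'   noise (>= 0).
#' @param seed integer seed.
#' @return an \code{\link{ExpressionDataset}}.
#' @examples
#' x <- simulateExpression(50, treatments = 2, replicates = 2, seed = 1)
#' @export
simulateExpression <- function(nGenes, treatments = 2, replicates = 2,
                               logMean = log(100), logSd = 1,
                               effects = NULL, replicateNoiseSd = 0,
                               seed = 1) {
    if (nGenes < 1) stop("nGenes must be >= 1")
    if (replicateNoiseSd < 0) stop("replicateNoiseSd must be >= 0")
    tl <- if (is.character(treatments)) treatments
          else paste0("T", seq_len(treatments))
    rl <- if (is.character(replicates)) replicates
          else paste0("R", seq_len(replicates))
    n <- length(tl); r <- length(rl)
    if (n < 1 || r < 1) stop("need >= 1 treatment and replicate")
    if (is.null(effects)) effects <- matrix(1, nGenes, n)
    else if (is.vector(effects) && length(effects) == n)
        effects <- matrix(rep(effects, each = nGenes), nGenes, n)
    else if (!(is.matrix(effects) && all(dim(effects) == c(nGenes, n))))
        stop("effects must be NULL, length-", n,
             " vector, or ", nGenes, "x", n, " matrix")
    if (any(effects <= 0)) stop("effects must be positive")
    .withSeed(seed, {
        baseline <- exp(stats::rnorm(nGenes, logMean, logSd))
        vals <- matrix(NA_real_, nGenes, n * r)
        cn <- character(n * r)
        lay <- data.frame(sample = character(n * r),
                          treatment = character(n * r),
                          replicate = character(n * r))
        j <- 0L
        for (t in seq_len(n)) for (k in seq_len(r)) {
            j <- j + 1L
            noise <- if (replicateNoiseSd > 0)
                exp(stats::rnorm(nGenes, 0, replicateNoiseSd)) else 1
            vals[, j] <- baseline * effects[, t] * noise
            cn[j] <- paste0(tl[t], "_", rl[k])
            lay[j, ] <- c(cn[j], tl[t], rl[k])
        }
        dimnames(vals) <- list(paste0("g", seq_len(nGenes)), cn)
        ExpressionDataset(vals, lay, metadata = list(
            simulation = list(nGenes = nGenes, treatments = tl,
                              replicates = rl, logMean = logMean,
                              logSd = logSd,
                              replicateNoiseSd = replicateNoiseSd,
                              seed = seed)))
    })
}

#' Replicate-noise level that gives a target fold-exceedance probability
#'
#' For log-normal multiplicative replicate noise with log-sd \eqn{\sigma},
#' the ratio of two replicate values of one gene is log-normal with log-sd
#' \eqn{\sigma\sqrt{2}}, so
#' \deqn{P(\max/\min \ge f) = 2\,\Phi(-\ln f / (\sigma\sqrt{2})).}
#' This inverts that relation: it returns the \eqn{\sigma} at which a
#' fraction \code{p} of genes shows an inter-replicate fold change of at
#' least \code{fold} (equivalently, inter-replicate variation of at least
#' \code{fold - 1}).
#'
#' @param p target exceedance probability in (0, 1).
#' @param fold fold-change level (> 1), e.g. 1.5 for "50\% variation".
#' @return the log-scale noise sd.
#' @examples
#' noiseSdForExceedance(0.65)   # ~65% of genes beyond 1.5-fold
#' @export
noiseSdForExceedance <- function(p, fold = 1.5) {
    stopifnot(p > 0, p < 1, fold > 1)
    -log(fold) / (sqrt(2) * stats::qnorm(p / 2))
}

#' Simulate a paired transcript/protein table with a length-coupled
#' translation mechanism
#'
#' Emulates the translation-time argument behind the ORF-length correction:
#' if two genes are induced equally at the transcript level but one coding
#' sequence is twice as long, the longer protein accumulates half as fast.
#' The observed protein fold change is generated as
#' \deqn{PF_i = p_i / CF_i \cdot \epsilon_i}
#' where \eqn{CF_i = L_i / \min_j L_j} is the length correction factor,
#' \eqn{p_i} is the gene's intrinsic (length-free) protein response —
#' by default the transcript fold change itself — and \eqn{\epsilon_i} is
#' multiplicative log-normal noise. With \code{noiseSd = 0},
#' \code{\link{correctProtein}} inverts the mechanism exactly:
#' \code{CPF = PF * CF} equals the intrinsic response.
#'
#' @param lengths named vector of ORF lengths (bp), one per gene.
#' @param transcriptFold per-gene transcript fold change (positive; recycled).
#' @param proteinResponse per-gene intrinsic protein response before the
#'   length penalty; defaults to \code{transcriptFold}.
#' @param noiseSd log-scale sd of the multiplicative noise on PF.
#' @param seed integer seed.
#' @return a \code{\link{ProteinTranscriptTable}} with columns TF, PF, ORF.
#' @examples
#' simulateProteinTranscript(c(A = 1000, B = 2000), transcriptFold = 4)
#' @export
simulateProteinTranscript <- function(lengths, transcriptFold,
                                      proteinResponse = transcriptFold,
                                      noiseSd = 0, seed = 1) {
    if (!length(lengths) || is.null(names(lengths)))
        stop("'lengths' must be a named vector of ORF lengths")
    genes <- names(lengths)
    tf <- rep_len(transcriptFold, length(genes))
    pr <- rep_len(proteinResponse, length(genes))
    if (any(tf <= 0) || any(pr <= 0))
        stop("folds and responses must be positive")
    cf <- correctionFactors(lengths)
    .withSeed(seed, {
        noise <- if (noiseSd > 0)
            exp(stats::rnorm(length(genes), 0, noiseSd)) else 1
        ProteinTranscriptTable(gene = genes, TF = tf,
                               PF = pr / cf * noise,
                               ORF = unname(lengths))
    })
}
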