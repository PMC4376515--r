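#' Construct a ProteinTranscriptTable
#'
#' @param gene gene ids (unique).
#' @param TF transcript fold change or quantity (positive).
#' @param PF observed protein fold change or quantity (positive).
#' @param ORF coding-sequence length in bp (>= 1).
#' @return a \code{\link[=ProteinTranscriptTable-class]{ProteinTranscriptTable}}.
#' @export
ProteinTranscriptTable <- function(gene, TF, PF, ORF) {
    new("ProteinTranscriptTable",
        DataFrame(TF = as.numeric(TF), PF = as.numeric(PF),
                  ORF = as.integer(round(ORF)), row.names = gene))
}

#' ORF-length correction factors
#'
#' Translation of a coding sequence twice as long takes roughly twice as
#' much time, so equal transcript induction yields unequal protein
#' induction across genes of different lengths even without any
#' post-transcriptional regulation. The correction factor of gene i is its
#' ORF length divided by the shortest ORF length in the table:
#' \eqn{CF_i = L_i / \min_j L_j \ge 1}, with equality for the shortest
#' gene. CF is unitless and invariant to a common rescaling of all lengths.
#'
#' @param lengths positive lengths (named vector), bp.
#' @return numeric vector of correction factors (names preserved).
#' @examples
#' correctionFactors(c(a = 1000, b = 2000, c = 1500))  # 1, 2, 1.5
#' @export
correctionFactors <- function(lengths) {
    if (!length(lengths)) stop("empty length table")
    if (any(is.na(lengths)) || any(lengths < 1))
        stop("lengths must be >= 1")
    lengths / min(lengths)
}

#' Apply the ORF-length correction to protein values
#'
#' Adds the \code{CF} column (\code{\link{correctionFactors}} of the ORF
#' lengths) and the corrected protein value \code{CPF = PF * CF}. The
#' correction always multiplies the protein values and never divides the
#' transcript values. It applies identically to fold changes and to raw
#' quantities.
#'
#' @param table a \code{ProteinTranscriptTable} (or data.frame with columns
#'   \code{gene}, \code{TF}, \code{PF}, \code{ORF}).
#' @return the table with \code{CF} and \code{CPF} columns added.
#' @examples
#' tab <- ProteinTranscriptTable(gene = c("A", "B"), TF = c(2, 2),
#'                               PF = c(6, 9), ORF = c(5000, 2000))
#' correctProtein(tab)$CPF  # 15, 22.5 relative to min length 2000
#' @export
correctProtein <- function(table) {
    if (is.data.frame(table)) {
        need <- c("gene", "TF", "PF", "ORF")
        if (!all(need %in% colnames(table)))
            stop("table must have columns: ", paste(need, collapse = ", "))
        table <- ProteinTranscriptTable(table$gene, table$TF, table$PF,
                                        table$ORF)
    }
    stopifnot(is(table, "ProteinTranscriptTable"))
    if (any(is.na(table$ORF)))
        stop("missing ORF length for gene: ",
             rownames(table)[which(is.na(table$ORF))[1L]])
    cf <- correctionFactors(stats::setNames(as.numeric(table$ORF),
                                            rownames(table)))
    df <- DataFrame(TF = table$TF, PF = table$PF, ORF = table$ORF,
                    CF = unname(cf), CPF = table$PF * unname(cf),
                    row.names = rownames(table))
    out <- new("ProteinTranscriptTable", df)
    validObject(out)
    out
}

#' Correlation shift after ORF-length correction
#'
#' Pearson and Spearman correlations of transcript versus protein values,
#' before (observed protein) and after (protein times CF) the length
#' correction. A shift toward stronger agreement after correction indicates
#' that part of the apparent protein-mRNA discordance was the length
#' artifact rather than post-transcriptional regulation. A coefficient on a
#' constant vector is undefined and reported as \code{NA}, never as 0.
#'
#' @param transcript,protein named per-gene value vectors.
#' @param lengths named per-gene ORF lengths (bp).
#' @return a \code{\link[=CorrelationShift-class]{CorrelationShift}}.
#' @examples
#' L <- c(a = 1000, b = 2000, c = 4000)
#' tr <- c(a = 2, b = 3, c = 5)
#' pr <- tr / correctionFactors(L)       # pure length mechanism
#' correlationShift(tr, pr, L)           # rAfter = 1 exactly
#' @export
correlationShift <- function(transcript, protein, lengths) {
    genes <- names(transcript)
    if (is.null(genes) || is.null(names(protein)) || is.null(names(lengths)))
        stop("transcript, protein and lengths must be named by gene id")
    common <- intersect(intersect(genes, names(protein)), names(lengths))
    if (length(common) < 3L) stop("need >= 3 matched genes")
    tr <- transcript[common]; pr <- protein[common]
    cf <- correctionFactors(lengths[common])
    cpr <- pr * cf
    undef <- character()
    corOr <- function(xx, yy, method, label) {
        if (stats::var(xx) == 0 || stats::var(yy) == 0) {
            undef <<- c(undef, label)
            return(NA_real_)
        }
        stats::cor(xx, yy, method = method)
    }
    pOr <- function(xx, yy) {
        if (stats::var(xx) == 0 || stats::var(yy) == 0) return(NA_real_)
        stats::cor.test(xx, yy, alternative = "two.sided")$p.value
    }
    res <- new("CorrelationShift",
        rBefore = corOr(tr, pr, "pearson", "rBefore"),
        rAfter = corOr(tr, cpr, "pearson", "rAfter"),
        rhoBefore = corOr(tr, pr, "spearman", "rhoBefore"),
        rhoAfter = corOr(tr, cpr, "spearman", "rhoAfter"),
        pBefore = pOr(tr, pr), pAfter = pOr(tr, cpr),
        nGenes = length(common),
        table = DataFrame(transcript = unname(tr), protein = unname(pr),
                          ORF = unname(lengths[common]), CF = unname(cf),
                          correctedProtein = unname(cpr),
                          row.names = common),
        undefined = undef)
    res
}

#' Pearson and Spearman correlations with two-tailed p-values
#'
#' Generic paired-correlation utility (used e.g. for ORF length versus
#' ribosome counts or occupancy). Spearman uses average ranks on ties;
#' its p-value is the asymptotic t approximation. Constant inputs give
#' \code{NA} coefficients flagged in \code{undefined}.
#'
#' @param x,y numeric vectors (>= 3 pairs).
#' @return list with \code{pearson} (r, p), \code{spearman} (rho, p),
#'   \code{n} and \code{undefined}.
#' @export
rankCorrelations <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop("need >= 3 complete pairs")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        return(list(pearson = c(r = NA_real_, p = NA_real_),
                    spearman = c(rho = NA_real_, p = NA_real_),
                    n = length(x), undefined = c("pearson", "spearman")))
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    st <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           alternative = "two.sided"))
    list(pearson = c(r = unname(ct$estimate), p = ct$p.value),
         spearman = c(rho = unname(st$estimate), p = st$p.value),
         n = length(x), undefined = character())
}

setMethod("show", "CorrelationShift", function(object) {
    f <- function(v) ifelse(is.na(v), "undefined", format(v, digits = 3))
    cat("CorrelationShift over", object@nGenes, "genes\n",
        "  Pearson  r:  ", f(object@rBefore), "->", f(object@rAfter), "\n",
        "  Spearman rho:", f(object@rhoBefore), "->", f(object@rhoAfter),
        "\n")
    if (length(object@undefined))
        cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "ProteinTranscriptTable", function(object) {
    cat("ProteinTranscriptTable:", nrow(object), "genes",
        if ("CPF" %in% colnames(object)) "(length-corrected)" else
            "(uncorrected)", "\n")
    callNextMethod()
})
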