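# shared numeric helpers

# deviation-from-1 of a ratio: fold into [0, Inf) symmetrically
# (v and 1/v give the same deviation)
.foldDeviation <- function(v) ifelse(v >= 1, v - 1, 1 / v - 1)

.sdPop <- function(x) sqrt(mean((x - mean(x))^2))

.sdOf <- function(x, type = c("sample", "population")) {
    type <- match.arg(type)
    if (length(x) < 2L && type == "sample") return(NA_real_)
    if (type == "sample") stats::sd(x) else .sdPop(x)
}

# run expr with a local RNG stream; the caller's .Random.seed is untouched
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# guess the field separator of a delimited text file
.sniffDelim <- function(path) {
    line <- readLines(path, n = 1L)
    counts <- vapply(c("\t", ",", ";"), function(d)
        lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))), integer(1))
    if (all(counts == 0L))
        stop("cannot detect delimiter (none of tab/comma/semicolon) in ", path)
    c("\t", ",", ";")[which.max(counts)]
}

.fmtNum <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
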