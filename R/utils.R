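## Internal helpers.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

.assertScalarNumeric <- function(x, nm, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x))
        stop("'", nm, "' must be a single numeric value", call. = FALSE)
    ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
    if (!ok)
        stop("'", nm, "' must lie in ", if (strict) "(" else "[", lower,
             ", ", upper, if (strict) ")" else "]", call. = FALSE)
    invisible(x)
}

## Intersect a character vector with a universe, messaging the drop count.
.trimToUniverse <- function(genes, universe, what) {
    out <- intersect(genes, universe)
    dropped <- length(genes) - length(out)
    if (dropped > 0L)
        message(dropped, " gene(s) in ", what,
                " are outside the universe and were dropped")
    out
}

.asGeneIds <- function(x) {
    if (is(x, "GeneSet")) geneIds(x) else unique(as.character(x))
}

## Exact two-sided one-sample Wilcoxon signed-rank p-value for non-zero
## differences, by convolution of the sign-flip distribution over
## tie-averaged ranks (doubled to integers). Exact even with ties.
.exactSignedRankP <- function(d) {
    r2 <- as.integer(round(2 * rank(abs(d))))
    W <- sum(r2[d > 0])
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2)
        counts <- counts + c(rep(0, ri),
                             counts[seq_len(total + 1L - ri)])
    probs <- counts / 2^length(r2)
    pl <- sum(probs[seq_len(W + 1L)])
    pu <- sum(probs[(W + 1L):(total + 1L)])
    min(1, 2 * min(pl, pu))
}

## Two-sided one-sample signed-rank p-value on non-zero differences:
## exact (tie-tolerant) for n <= exactMax, otherwise the normal
## approximation with tie and continuity corrections.
.signedRankP <- function(d, exactMax = 25L) {
    if (length(d) <= exactMax) .exactSignedRankP(d)
    else suppressWarnings(
        wilcox.test(d, mu = 0, alternative = "two.sided", exact = FALSE,
                    correct = TRUE)$p.value)
}
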