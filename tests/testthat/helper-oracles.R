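## Independent brute-force oracles and small fixture builders. These are
## deliberately written against first principles (enumeration, closed
## forms) and share no code with the package implementation.

## Upper-tail hypergeometric P(X >= k) by direct tail summation.
bruteHyperTailP <- function(nUniverse, nB, nA, k) {
    j <- k:min(nA, nB)
    sum(choose(nB, j) * choose(nUniverse - nB, nA - j)) /
        choose(nUniverse, nA)
}

## Two-sided one-sample Wilcoxon signed-rank p by enumeration of all 2^n
## sign assignments over tie-averaged ranks.
bruteSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    wObs <- sum(r[d > 0])
    ws <- vapply(0:(2^n - 1), function(mask) {
        bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
        sum(r[bits])
    }, numeric(1L))
    pl <- mean(ws <= wObs + 1e-09)
    pu <- mean(ws >= wObs - 1e-09)
    min(1, 2 * min(pl, pu))
}

## Two-sided exact binomial p (minimum-likelihood method) by enumeration.
bruteBinomP <- function(x, n, p0) {
    dens <- dbinom(0:n, n, p0)
    sum(dens[dens <= dens[x + 1L] * (1 + 1e-07)])
}

## Benjamini-Hochberg step-up by hand: sort ascending, q_(i) = p_(i)*m/i,
## enforce monotonicity from the largest rank down, cap at 1.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in (m - 1L):1L) if (m > 1L) q[i] <- min(q[i], q[i + 1L])
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

## Power of the two-sided Fisher exact test by full enumeration with
## stats::fisher.test (independent of the package's dhyper-based path).
bruteFisherPower <- function(n1, p1, n2, p2, alpha) {
    pow <- 0
    for (x1 in 0:n1) for (x2 in 0:n2) {
        w <- dbinom(x1, n1, p1) * dbinom(x2, n2, p2)
        if (w == 0) next
        pv <- fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2L, 2L,
                                 byrow = TRUE))$p.value
        if (pv <= alpha) pow <- pow + w
    }
    pow
}

## A tiny well-formed DE table.
makeDETable <- function(n = 10L, contrastId = "toy", seed = 1L) {
    set.seed(seed)
    p <- runif(n)
    DETable(gene = sprintf("gene%03d", seq_len(n)),
            log2fc = rnorm(n), pvalue = p, padj = bhAdjust(p),
            expressed = TRUE, contrastId = contrastId)
}

## A small synthetic configuration for fast tests.
smallConfig <- function(seed = 7L, ...) {
    synthConfig(nGenes = 2000L, nShared = 150L, nAOnly = 80L,
                nBOnly = 80L,
                phaseSizes = c("G1/S" = 15L, "S" = 15L, "G2" = 15L,
                               "M" = 15L, "M/G1" = 15L),
                seed = seed, ...)
}
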