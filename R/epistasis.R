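## Correlation of fold-change vectors over dependent genes, bootstrap null
## from random gene sets, and the linear attenuation (epistasis) model.

## Extract the two aligned log2fc vectors of a merged pair, optionally
## restricted to a gene set.
.pairedLfc <- function(merged, response, predictor, genes = NULL) {
    stopifnot(is(merged, "MergedContrasts"))
    x <- .mergedCol(merged, "log2fc", predictor)
    y <- .mergedCol(merged, "log2fc", response)
    keep <- is.finite(x) & is.finite(y)
    if (!is.null(genes)) keep <- keep & merged$gene %in% .asGeneIds(genes)
    list(x = x[keep], y = y[keep], gene = merged$gene[keep])
}

#' Spearman correlation of fold changes over dependent genes
#'
#' Rank correlation between two contrasts' log2 fold changes restricted to
#' a dependent gene set, with the two-sided p-value that rho differs from
#' zero (via \code{stats::cor.test}).
#'
#' @param merged a [MergedContrasts-class] over two contrasts.
#' @param dependent the restriction [GeneSet-class] (or character vector);
#'   at least 3 of its genes must be present in the merged table.
#' @param response,predictor contrast labels; default to the second and
#'   first merged contrast.
#' @return A list with \code{rho}, \code{pvalue} and \code{n}.
#' @export
spearmanDependent <- function(merged, dependent,
                              response = contrastIds(merged)[2L],
                              predictor = contrastIds(merged)[1L]) {
    v <- .pairedLfc(merged, response, predictor, dependent)
    if (length(v$x) < 3L)
        stop("need at least 3 dependent genes in the merged table, got ",
             length(v$x))
    ct <- suppressWarnings(
        cor.test(v$x, v$y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), pvalue = ct$p.value, n = length(v$x))
}

#' Bootstrap null distribution for a gene-set Spearman correlation
#'
#' Draws \code{nIter} gene sets of size \code{setSize} without replacement
#' (independently across iterations) from the merged expressed universe,
#' records the Spearman correlation of the two fold-change vectors
#' restricted to each set, and standardises the observed correlation
#' against this null: \code{zObs = (rhoObs - mean) / sd}. The p-value is
#' the one-sided upper-tail normal probability, reported on the natural-log
#' scale so that extreme enrichments do not underflow.
#'
#' @param merged a [MergedContrasts-class] over two contrasts.
#' @param setSize number of genes per random set (at most the number of
#'   merged genes); typically the dependent-set size.
#' @param rhoObs the observed correlation to standardise.
#' @param nIter number of random sets (>= 100; the field-standard choice
#'   is 1e5).
#' @param seed integer seed; identical seeds give identical draws.
#' @param response,predictor contrast labels as in [spearmanDependent()].
#' @return A [BootstrapNull-class].
#' @export
bootstrapNullRho <- function(merged, setSize, rhoObs, nIter = 100000L,
                             seed = 1L,
                             response = contrastIds(merged)[2L],
                             predictor = contrastIds(merged)[1L]) {
    v <- .pairedLfc(merged, response, predictor)
    n <- length(v$x)
    setSize <- as.integer(setSize)
    nIter <- as.integer(nIter)
    if (setSize > n)
        stop("'setSize' (", setSize, ") exceeds the merged universe (",
             n, ")")
    if (setSize < 3L) stop("'setSize' must be at least 3")
    if (nIter < 100L) stop("'nIter' must be at least 100")
    rhos <- withSeed(seed, {
        vapply(seq_len(nIter), function(i) {
            idx <- sample.int(n, setSize)
            cor(v$x[idx], v$y[idx], method = "spearman")
        }, numeric(1L))
    })
    mu <- mean(rhos)
    s <- sd(rhos)
    z <- (rhoObs - mu) / s
    new("BootstrapNull", nIter = nIter, setSize = setSize,
        nullRhos = rhos, mean = mu, sd = s, rhoObs = rhoObs, zObs = z,
        logP = pnorm(z, lower.tail = FALSE, log.p = TRUE),
        seed = as.integer(seed))
}

#' Fit the linear attenuation (epistasis) model
#'
#' Ordinary least squares of the response contrast's log2 fold changes on
#' the predictor contrast's, over a dependent gene set (by default the
#' genes regulated by the predictor contrast at adjusted p <
#' \code{alpha}, up and down combined). The slope estimates how much of the
#' predictor knockout's transcriptomic program is retained in the response
#' contrast: 1 means full effect, 0 none, values between partial
#' (attenuated) activity. The 95\% confidence interval uses the t
#' distribution with n - 2 degrees of freedom. The Spearman correlation of
#' the same restricted vectors is reported alongside.
#'
#' @param merged a [MergedContrasts-class] over two contrasts.
#' @param dependent optional restriction [GeneSet-class]; when \code{NULL},
#'   the predictor contrast's regulated genes at \code{alpha} are used.
#' @param response,predictor contrast labels; default response = second,
#'   predictor = first merged contrast.
#' @param alpha adjusted-p threshold for the default dependent set.
#' @return An [EpistasisFit-class].
#' @examples
#' a <- DETable(letters[1:5], c(0, 1, 2, 3, 4), 0.001, 0.01,
#'              contrastId = "A")
#' b <- DETable(letters[1:5], c(0, 0.5, 1, 1.5, 2), 0.001, 0.01,
#'              contrastId = "B")
#' fitAttenuation(mergeByGene(list(a, b)), dependent = letters[1:5])
#' @export
fitAttenuation <- function(merged, dependent = NULL,
                           response = contrastIds(merged)[2L],
                           predictor = contrastIds(merged)[1L],
                           alpha = 0.05) {
    stopifnot(is(merged, "MergedContrasts"))
    if (is.null(dependent)) {
        padj <- .mergedCol(merged, "padj", predictor)
        lfc <- .mergedCol(merged, "log2fc", predictor)
        dependent <- merged$gene[!is.na(padj) & padj < alpha & lfc != 0]
    }
    v <- .pairedLfc(merged, response, predictor, dependent)
    n <- length(v$x)
    if (n < 3L)
        stop("need at least 3 dependent genes in the merged table, got ", n)
    if (var(v$x) == 0)
        stop("zero variance in the predictor log2 fold changes")
    fit <- lm(y ~ x, data = list(x = v$x, y = v$y))
    ci <- confint(fit, "x", level = 0.95)
    sp <- suppressWarnings(
        cor.test(v$x, v$y, method = "spearman", exact = FALSE))
    new("EpistasisFit", nGenes = as.integer(n),
        rho = unname(sp$estimate), rhoP = sp$p.value,
        slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
        slopeSE = summary(fit)$coefficients["x", "Std. Error"],
        ci95 = as.numeric(ci),
        responseContrast = response, predictorContrast = predictor)
}

#' Paired comparison of two contrasts' fold changes over a gene list
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-gene differences
#' of log2 fold changes between the two contrasts, over a listed gene set —
#' the "are these fold changes statistically similar as a group" question.
#' If every paired difference is zero the signed-rank statistic is
#' undefined; the p-value is reported as 1 with a warning (a conservative
#' convention). The exact distribution (tie-tolerant, by convolution over
#' tie-averaged ranks) is used for at most 25 non-zero differences.
#'
#' @param merged a [MergedContrasts-class] over two contrasts.
#' @param genes the gene list ([GeneSet-class] or character); at least two
#'   must be present in the merged table.
#' @param contrastX,contrastY the two contrast labels (defaults: first and
#'   second merged contrast); differences are \code{contrastX - contrastY}.
#' @return A list with \code{pvalue}, \code{n} and \code{table}, a
#'   \linkS4class{DFrame} of the per-gene fold changes for plotting.
#' @export
comparePairedLfc <- function(merged, genes,
                             contrastX = contrastIds(merged)[1L],
                             contrastY = contrastIds(merged)[2L]) {
    v <- .pairedLfc(merged, contrastY, contrastX, genes)
    n <- length(v$x)
    if (n < 2L)
        stop("need at least 2 listed genes in the merged table, got ", n)
    d <- v$x - v$y
    nz <- d[d != 0]
    p <- if (length(nz) == 0L) {
        warning("all paired differences are zero; p-value reported as 1",
                call. = FALSE)
        1
    } else .signedRankP(nz)
    tab <- DataFrame(gene = v$gene)
    tab[[paste0("log2fc_", contrastX)]] <- v$x
    tab[[paste0("log2fc_", contrastY)]] <- v$y
    list(pvalue = p, n = n, table = tab)
}
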