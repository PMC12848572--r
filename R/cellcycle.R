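## Cell-cycle phase percentile-rank scoring.

#' Percentile ranks of genes by log2 fold change
#'
#' Ranks the expressed genes of a contrast by log2 fold change (ascending)
#' and rescales to \code{[0, 1]} as \code{(rank - 1) / (N - 1)}, averaging
#' tied values' ranks. Under this convention the minimum is 0, the maximum
#' is 1, and the median over all genes is 0.5 for distinct values — the
#' reference the phase test compares against.
#'
#' @param table a [DETable-class] with at least two expressed genes with
#'   finite log2 fold change.
#' @return A named numeric vector of percentile ranks in \code{[0, 1]}.
#' @examples
#' tab <- DETable(letters[1:4], c(-2, -1, 1, 2), contrastId = "demo")
#' percentileRanks(tab)
#' @export
percentileRanks <- function(table) {
    stopifnot(is(table, "DETable"))
    keep <- table$expressed & is.finite(table$log2fc)
    lfc <- setNames(table$log2fc[keep], table$gene[keep])
    n <- length(lfc)
    if (n < 2L) stop("need at least 2 expressed genes with finite log2fc")
    (rank(lfc, ties.method = "average") - 1) / (n - 1)
}

#' Per-phase percentile-rank scores and signed-rank tests
#'
#' For each cell-cycle phase, summarises the percentile ranks of its
#' annotated genes (median and interquartile range) and tests whether they
#' deviate from the all-gene median of 0.5 with a two-sided one-sample
#' Wilcoxon signed-rank test on \code{rank - 0.5}. P-values are BH-adjusted
#' across exactly the phases tested (the phases of one contrast form the
#' family). The exact null distribution (computed by convolution over
#' tie-averaged ranks, so ties are handled exactly) is used when a phase
#' has at most 25 usable genes; otherwise the normal approximation with
#' tie and continuity corrections. Genes whose rank is exactly 0.5 are dropped from the test
#' (their count is messaged) but still contribute to the summaries.
#'
#' @param ranks named numeric vector from [percentileRanks()].
#' @param phases a [PhaseAnnotation-class]. Annotated genes absent from
#'   \code{ranks} are excluded with a message; a phase with no matched genes
#'   is an error.
#' @return A \linkS4class{DFrame} with one row per phase in the canonical
#'   order of [CELL_CYCLE_PHASES] (restricted to annotated phases) and
#'   columns \code{phase}, \code{n}, \code{median_rank}, \code{q1},
#'   \code{q3}, \code{pvalue}, \code{padj}.
#' @examples
#' tab <- DETable(sprintf("g%02d", 1:20), seq(-2, 2, length.out = 20),
#'                contrastId = "demo")
#' ann <- PhaseAnnotation(c("g01", "g02", "g03", "g18", "g19", "g20"),
#'                        rep(c("G1/S", "M"), each = 3))
#' phaseScoreTest(percentileRanks(tab), ann)
#' @export
phaseScoreTest <- function(ranks, phases) {
    stopifnot(is(phases, "PhaseAnnotation"))
    ph <- phaseOf(phases)
    absent <- sum(!names(ph) %in% names(ranks))
    if (absent > 0L)
        message(absent, " annotated gene(s) absent from the ranked table ",
                "were excluded")
    ph <- ph[names(ph) %in% names(ranks)]
    phaseLevels <- CELL_CYCLE_PHASES[CELL_CYCLE_PHASES %in%
                                     unique(phaseOf(phases))]
    rows <- lapply(phaseLevels, function(p) {
        g <- names(ph)[ph == p]
        if (length(g) == 0L)
            stop("phase ", sQuote(p), " has no annotated genes in the ",
                 "ranked table")
        r <- ranks[g]
        d <- r - 0.5
        nz <- d[d != 0]
        if (length(nz) < length(d))
            message(length(d) - length(nz), " gene(s) in phase ",
                    sQuote(p), " at rank exactly 0.5 dropped from the test")
        pval <- if (length(nz) == 0L) {
            warning("all ranks in phase ", sQuote(p),
                    " equal 0.5; p-value reported as 1", call. = FALSE)
            1
        } else .signedRankP(nz)
        q <- unname(quantile(r, c(0.25, 0.5, 0.75)))
        DataFrame(phase = p, n = length(r), median_rank = q[2L],
                  q1 = q[1L], q3 = q[3L], pvalue = pval)
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$pvalue)
    out
}
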