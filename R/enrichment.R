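## Gene-set overlap enrichment and quadrant classification.

#' One-tailed hypergeometric overlap test
#'
#' Tests whether two gene sets overlap more than expected by chance when
#' both are drawn from a common universe. The p-value is the inclusive
#' upper tail \eqn{P(X \ge k)} for \eqn{X \sim}
#' Hypergeometric(universe, |B|, |A|) with observed overlap \eqn{k} — an
#' enrichment-only test, symmetric in the two sets. Genes outside the
#' universe are dropped with a message, never added.
#'
#' @param setA,setB [GeneSet-class] objects (or character vectors).
#' @param universe the background [GeneSet-class] (or character vector),
#'   typically all expressed genes.
#' @return An [OverlapTest-class]; \code{padj} is \code{NA} until a family
#'   adjustment is applied (see [adjustOverlapFamily()]).
#' @examples
#' u <- sprintf("g%02d", 1:10)
#' hypergeomOverlap(GeneSet("A", u[1:4]), GeneSet("B", u[c(1:3, 9:10)]), u)
#' @export
hypergeomOverlap <- function(setA, setB, universe) {
    u <- .asGeneIds(universe)
    if (length(u) == 0L) stop("the universe is empty")
    aName <- if (is(setA, "GeneSet")) setName(setA) else "setA"
    bName <- if (is(setB, "GeneSet")) setName(setB) else "setB"
    a <- .trimToUniverse(.asGeneIds(setA), u, sQuote(aName))
    b <- .trimToUniverse(.asGeneIds(setB), u, sQuote(bName))
    k <- length(intersect(a, b))
    ## P(X >= k), inclusive of the observed overlap
    p <- phyper(k - 1L, length(b), length(u) - length(b), length(a),
                lower.tail = FALSE)
    new("OverlapTest", setAName = aName, setBName = bName,
        nUniverse = length(u), nA = length(a), nB = length(b),
        nOverlap = as.integer(k), pvalue = p, padj = NA_real_)
}

#' BH-adjust a family of overlap tests
#'
#' The family is exactly the list the caller submits together (for example,
#' the tests displayed in one figure panel).
#'
#' @param tests a list of [OverlapTest-class] objects.
#' @return The same list with \code{padj} filled in.
#' @export
adjustOverlapFamily <- function(tests) {
    stopifnot(is.list(tests),
              all(vapply(tests, is, logical(1L), "OverlapTest")))
    padj <- bhAdjust(vapply(tests, function(t) t@pvalue, numeric(1L)))
    for (i in seq_along(tests)) tests[[i]]@padj <- padj[i]
    tests
}

#' Tidy data.frame of overlap tests
#'
#' @param tests a list of [OverlapTest-class] objects.
#' @return A \linkS4class{DFrame} with one row per test.
#' @export
overlapTable <- function(tests) {
    if (is(tests, "OverlapTest")) tests <- list(tests)
    do.call(rbind, lapply(tests, function(t)
        DataFrame(set_a = t@setAName, set_b = t@setBName,
                  n_universe = t@nUniverse, n_a = t@nA, n_b = t@nB,
                  n_overlap = t@nOverlap, pvalue = t@pvalue,
                  padj = t@padj)))
}

#' Classify genes of a two-contrast merged table into regulation quadrants
#'
#' Each gene significant (adjusted p < \code{alpha}) in at least one
#' contrast is assigned to exactly one category: up in both, up in A only,
#' up in B only, down in both, down in A only, down in B only, or
#' discordant (significantly up in one contrast and down in the other).
#' "Only" means significant in that contrast and not significant in the
#' other. Genes significant in neither contrast are uncategorised.
#'
#' @param merged a [MergedContrasts-class] over exactly two contrasts.
#' @param alpha adjusted-p threshold in (0, 1).
#' @return A list with \code{counts} (named integer vector over the seven
#'   categories) and \code{sets} (named list of [GeneSet-class]).
#' @export
classifyQuadrants <- function(merged, alpha = 0.05) {
    stopifnot(is(merged, "MergedContrasts"))
    if (length(contrastIds(merged)) != 2L)
        stop("quadrant classification needs exactly two contrasts")
    .assertScalarNumeric(alpha, "alpha", 0, 1, strict = TRUE)
    ids <- contrastIds(merged)
    sigA <- !is.na(.mergedCol(merged, "padj", ids[1L])) &
        .mergedCol(merged, "padj", ids[1L]) < alpha
    sigB <- !is.na(.mergedCol(merged, "padj", ids[2L])) &
        .mergedCol(merged, "padj", ids[2L]) < alpha
    upA <- sigA & .mergedCol(merged, "log2fc", ids[1L]) > 0
    dnA <- sigA & .mergedCol(merged, "log2fc", ids[1L]) < 0
    upB <- sigB & .mergedCol(merged, "log2fc", ids[2L]) > 0
    dnB <- sigB & .mergedCol(merged, "log2fc", ids[2L]) < 0
    cats <- list(
        up_both = upA & upB,
        up_a_only = upA & !sigB,
        up_b_only = upB & !sigA,
        down_both = dnA & dnB,
        down_a_only = dnA & !sigB,
        down_b_only = dnB & !sigA,
        discordant = (upA & dnB) | (dnA & upB))
    sets <- lapply(names(cats), function(nm)
        GeneSet(nm, merged$gene[cats[[nm]]]))
    names(sets) <- names(cats)
    list(counts = vapply(cats, sum, integer(1L)), sets = sets)
}

#' Fraction of a query set covered by "activated" genes
#'
#' Activated genes are those upregulated in the reference contrast and
#' bound at the promoter in external binding data. Returns the fraction of
#' the query inside the activated set and the one-tailed hypergeometric
#' enrichment of activated genes within the query.
#'
#' @param query a non-empty [GeneSet-class] (or character vector).
#' @param upregulatedB genes upregulated in the reference contrast.
#' @param promoterBound promoter-bound genes from external binding data.
#' @param universe background gene set (all expressed genes).
#' @return A list with \code{fraction}, \code{activated} (the intersection
#'   as a [GeneSet-class]) and \code{test} (an [OverlapTest-class]).
#' @export
activatedFraction <- function(query, upregulatedB, promoterBound,
                              universe) {
    u <- .asGeneIds(universe)
    q <- .trimToUniverse(.asGeneIds(query), u, "the query set")
    if (length(q) == 0L) stop("the query set is empty")
    act <- intersect(
        .trimToUniverse(.asGeneIds(upregulatedB), u,
                        "the upregulated set"),
        .trimToUniverse(.asGeneIds(promoterBound), u,
                        "the promoter-bound set"))
    activated <- GeneSet("activated", act)
    qName <- if (is(query, "GeneSet")) setName(query) else "query"
    test <- hypergeomOverlap(GeneSet(qName, q), activated, u)
    list(fraction = length(intersect(q, act)) / length(q),
         activated = activated, test = test)
}

#' Enrichment of a query set against a gene-set collection
#'
#' One [hypergeomOverlap()] per collection set, BH-adjusted across the
#' collection (the collection is the multiple-testing family) and sorted by
#' adjusted p.
#'
#' @param query a [GeneSet-class] (or character vector).
#' @param collection a non-empty list of [GeneSet-class] objects.
#' @param universe background gene set.
#' @param alpha significance threshold recorded in the \code{significant}
#'   column.
#' @return A \linkS4class{DFrame} of [overlapTable()] rows sorted by
#'   \code{padj}, with a \code{significant} flag.
#' @export
enrichGeneSets <- function(query, collection, universe, alpha = 0.05) {
    if (!is.list(collection) || length(collection) < 1L)
        stop("'collection' must be a non-empty list of gene sets")
    tests <- lapply(collection, function(s)
        hypergeomOverlap(query, s, universe))
    tests <- adjustOverlapFamily(tests)
    out <- overlapTable(tests)
    out <- out[order(out$padj, out$pvalue), ]
    out$significant <- out$padj < alpha
    out
}
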