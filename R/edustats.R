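## Proportion statistics for labeling-index (EdU) count tables.

.checkCountTable <- function(table) {
    req <- c("group", "positive", "negative")
    if (!is.data.frame(table) || !all(req %in% colnames(table)))
        stop("a count table needs columns 'group', 'positive', 'negative'")
    if (any(table$positive < 0) || any(table$negative < 0))
        stop("counts must be non-negative")
    if (any(table$positive + table$negative < 1))
        stop("row(s) with zero total count: ",
             paste(table$group[table$positive + table$negative < 1],
                   collapse = ", "))
    if (anyDuplicated(table$group))
        stop("group labels must be unique")
    invisible(table)
}

#' Chi-squared test of homogeneity with BH-adjusted pairwise post-hocs
#'
#' Pearson chi-squared test on the groups-by-(positive, negative) table.
#' When the omnibus test rejects at \code{alpha}, all pairwise 2x2 tests
#' are run and BH-adjusted across the \eqn{k(k-1)/2} pairs. Following base
#' R conventions, the Yates continuity correction is applied to 2x2 tables
#' (including the pairwise post-hocs) and no correction to larger tables.
#' A warning is issued when any expected cell count falls below 1.
#'
#' @param table data.frame with columns \code{group}, \code{positive},
#'   \code{negative}; at least two rows.
#' @param alpha omnibus significance threshold gating the post-hocs.
#' @param posthoc \code{"auto"} (pairwise tests only when the omnibus test
#'   rejects at \code{alpha}), \code{"always"} or \code{"never"}.
#' @return A list with \code{statistic}, \code{df}, \code{pvalue} and
#'   \code{posthoc} (a data.frame of pairwise tests with \code{padj}, or
#'   \code{NULL} when post-hocs were not run).
#' @examples
#' tab <- data.frame(group = c("WT", "KO_A", "KO_B"),
#'                   positive = c(45, 30, 150), negative = c(955, 970, 850))
#' chisqHomogeneity(tab)
#' @export
chisqHomogeneity <- function(table, alpha = 0.05,
                             posthoc = c("auto", "always", "never")) {
    posthocMode <- match.arg(posthoc)
    .checkCountTable(table)
    if (nrow(table) < 2L)
        stop("homogeneity tests need at least two groups")
    m <- as.matrix(table[, c("positive", "negative")])
    rownames(m) <- table$group
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 1))
        warning("expected cell count(s) below 1; the chi-squared ",
                "approximation may be poor", call. = FALSE)
    omni <- suppressWarnings(chisq.test(m))
    runPosthoc <- switch(posthocMode,
                         auto = omni$p.value < alpha,
                         always = TRUE,
                         never = FALSE)
    posthoc <- NULL
    if (runPosthoc && nrow(m) > 2L) {
        pairs <- utils::combn(nrow(m), 2L)
        posthoc <- data.frame(
            group1 = table$group[pairs[1L, ]],
            group2 = table$group[pairs[2L, ]],
            statistic = NA_real_, pvalue = NA_real_,
            stringsAsFactors = FALSE)
        for (j in seq_len(ncol(pairs))) {
            ct <- suppressWarnings(chisq.test(m[pairs[, j], ]))
            posthoc$statistic[j] <- unname(ct$statistic)
            posthoc$pvalue[j] <- ct$p.value
        }
        posthoc$padj <- bhAdjust(posthoc$pvalue)
    } else if (runPosthoc && nrow(m) == 2L) {
        ## with two groups the omnibus already is the pairwise test
        posthoc <- data.frame(group1 = table$group[1L],
                              group2 = table$group[2L],
                              statistic = unname(omni$statistic),
                              pvalue = omni$p.value,
                              padj = omni$p.value,
                              stringsAsFactors = FALSE)
    }
    list(statistic = unname(omni$statistic),
         df = unname(omni$parameter), pvalue = omni$p.value,
         posthoc = posthoc)
}

#' Exact binomial test (two-sided, minimum-likelihood method)
#'
#' Two-sided exact test of \code{positive} successes in \code{n} trials
#' against success probability \code{p0}: the p-value sums the
#' probabilities of all outcomes whose point probability does not exceed
#' that of the observed outcome (the convention of
#' \code{stats::binom.test}, which performs the computation).
#'
#' @param positive observed successes, \code{0 <= positive <= n}.
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @return The two-sided exact p-value.
#' @examples
#' exactBinomTest(0, 10, 0.5)   # 2/1024
#' @export
exactBinomTest <- function(positive, n, p0) {
    .assertScalarNumeric(p0, "p0", 0, 1, strict = TRUE)
    if (positive < 0 || positive > n)
        stop("'positive' must lie in [0, n]")
    binom.test(positive, n, p = p0,
               alternative = "two.sided")$p.value
}

## Two-sided Fisher exact p for the 2x2 table
## (x1, n1-x1; x2, n2-x2), minimum-likelihood rule, via the conditional
## hypergeometric distribution. Vectorised over x1.
.fisher2x2P <- function(x1, n1, x2, n2) {
    vapply(x1, function(a) {
        k <- a + x2
        support <- max(0L, k - n2):min(k, n1)
        dens <- dhyper(support, n1, n2, k)
        obs <- dens[match(a, support)]
        sum(dens[dens <= obs * (1 + 1e-07)])
    }, numeric(1L))
}

## Power of the Fisher exact test (two-sided, level alpha) to detect
## p1 vs p2 with group sizes n1, n2. Outcomes of each group are
## enumerated over a binomial support truncated to total tail mass
## < 1e-12 per side.
.fisherPower <- function(n1, p1, n2, p2, alpha) {
    support <- function(n, p) {
        if (p == 0) return(list(x = 0L, w = 1))
        if (p == 1) return(list(x = n, w = 1))
        x <- qbinom(1e-12, n, p):qbinom(1 - 1e-12, n, p)
        list(x = x, w = dbinom(x, n, p))
    }
    s1 <- support(n1, p1)
    s2 <- support(n2, p2)
    pow <- 0
    for (j in seq_along(s2$x)) {
        pvals <- .fisher2x2P(s1$x, n1, s2$x[j], n2)
        pow <- pow + s2$w[j] * sum(s1$w[pvals <= alpha])
    }
    pow
}

## Power of the large-sample two-proportion z-test with pooled variance
## under the null (the classic unequal-sample-size formula).
.approxPower <- function(n1, p1, n2, p2, alpha) {
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    za <- qnorm(1 - alpha / 2)
    delta <- abs(p1 - p2)
    pnorm((delta - za * se0) / se1) + pnorm((-delta - za * se0) / se1)
}

## Power of the exact one-sample binomial test of group 2 against the
## known proportion p1 (the n1 = Inf limit), using the central (doubled
## single-tail) two-sided convention.
.oneSamplePower <- function(p1, n2, p2, alpha) {
    x2 <- 0:n2
    pvals <- pmin(1, 2 * pmin(pbinom(x2, n2, p1),
                              pbinom(x2 - 1, n2, p1, lower.tail = FALSE)))
    sum(dbinom(x2, n2, p2)[pvals <= alpha])
}

#' Power of a two-sample comparison of proportions with unequal sizes
#'
#' @param n1,p1 reference-group size and true positive proportion.
#' @param n2,p2 test-group size and true positive proportion.
#' @param alpha two-sided significance level.
#' @param method \code{"approximate"} (default): the classic large-sample
#'   two-proportion z-test with variance pooled under the null;
#'   \code{"exact"}: the Fisher exact conditional test, with group outcomes
#'   enumerated exactly (binomial tails truncated below 1e-12 total mass).
#'   With \code{n1 = Inf}, \code{p1} is treated as known and power is
#'   computed for the exact one-sample binomial test of the test group
#'   against \code{p1} (central two-sided convention).
#' @return The probability of rejecting equality of proportions.
#' @seealso [minNForPower()]
#' @export
powerTwoProportions <- function(n1, p1, n2, p2, alpha = 0.05,
                                method = c("approximate", "exact")) {
    method <- match.arg(method)
    .assertScalarNumeric(p1, "p1", 0, 1)
    .assertScalarNumeric(p2, "p2", 0, 1)
    .assertScalarNumeric(alpha, "alpha", 0, 1, strict = TRUE)
    if (is.infinite(n1)) {
        if (method != "exact")
            stop("n1 = Inf (known reference proportion) requires ",
                 "method = \"exact\"")
        return(.oneSamplePower(p1, n2, p2, alpha))
    }
    if (method == "exact") .fisherPower(n1, p1, n2, p2, alpha)
    else .approxPower(n1, p1, n2, p2, alpha)
}

#' Minimum test-group size for a two-sample comparison of proportions
#'
#' Smallest \code{n2} such that the probability of rejecting equality of
#' proportions at two-sided level \code{alpha}, under independent
#' Binomial(\code{n1}, \code{p1}) and Binomial(\code{n2}, \code{p2})
#' sampling, reaches \code{power}. The search ascends in \code{n2} and
#' returns the first crossing.
#'
#' Two rejection rules are available (see [powerTwoProportions()]): the
#' default large-sample z-test with pooled null variance — the rule behind
#' the standard unequal-sample-size power formulas — and the exact
#' conditional (Fisher) test. On typical inputs the two agree to within one
#' cell; where they differ the choice of rule should be reported with the
#' result.
#'
#' @param p1,n1 reference-group proportion and size (\code{n1 = Inf} treats
#'   \code{p1} as known; exact method only).
#' @param p2 test-group true proportion; must differ from \code{p1}.
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @param method \code{"approximate"} or \code{"exact"}.
#' @param nMax search cap; exceeded is an error.
#' @return The minimal \code{n2} (integer).
#' @examples
#' ## known reference proportion, all-negative test group:
#' ## smallest n with 0.955^n <= alpha/2
#' minNForPower(p1 = 0.045, n1 = Inf, p2 = 0, power = 0.8,
#'              method = "exact")
#' @export
minNForPower <- function(p1, n1, p2, power = 0.8, alpha = 0.05,
                         method = c("approximate", "exact"),
                         nMax = 1e6L) {
    method <- match.arg(method)
    .assertScalarNumeric(p1, "p1", 0, 1)
    .assertScalarNumeric(p2, "p2", 0, 1)
    .assertScalarNumeric(power, "power", 0, 1, strict = TRUE)
    .assertScalarNumeric(alpha, "alpha", 0, 1, strict = TRUE)
    if (p1 == p2)
        stop("p1 and p2 are equal; the requested power is unattainable")
    for (n2 in seq_len(nMax)) {
        if (powerTwoProportions(n1, p1, n2, p2, alpha, method) >= power)
            return(n2)
    }
    stop("no n2 up to ", nMax, " reaches the requested power")
}
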