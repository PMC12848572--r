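## S4 class definitions and validity methods.

#' DETable: per-gene differential expression for one knockout contrast
#'
#' A \linkS4class{DFrame} with columns \code{gene}, \code{log2fc},
#' \code{pvalue}, \code{padj} and \code{expressed}, plus a contrast
#' identifier. Log2 fold changes are oriented wild-type over knockout, so a
#' positive value means the knocked-out factor upregulates the gene.
#'
#' Validity requires unique gene symbols, finite \code{log2fc} for every
#' expressed gene, and \code{padj >= pvalue} wherever both are present.
#'
#' @slot contrastId single character label, e.g. \code{"WT_vs_MeiocKO"}.
#' @seealso [DETable()], [readDETable()], [defineRegulatedSets()]
#' @aliases DETable-class
#' @exportClass DETable
setClass("DETable",
    contains = "DFrame",
    representation(contrastId = "character"))

.validDETable <- function(object) {
    msg <- NULL
    req <- c("gene", "log2fc", "pvalue", "padj", "expressed")
    if (!all(req %in% colnames(object)))
        return(paste0("missing column(s): ",
                      paste(setdiff(req, colnames(object)), collapse = ", ")))
    if (length(object@contrastId) != 1L || is.na(object@contrastId) ||
        !nzchar(object@contrastId))
        msg <- c(msg, "'contrastId' must be a single non-empty string")
    g <- object$gene
    if (anyDuplicated(g)) {
        dup <- unique(g[duplicated(g)])
        msg <- c(msg, paste0("duplicate gene symbol(s): ",
                             paste(head(dup, 5L), collapse = ", ")))
    }
    bad <- object$expressed & !is.finite(object$log2fc)
    if (any(bad))
        msg <- c(msg, "log2fc must be finite for every expressed gene")
    both <- !is.na(object$pvalue) & !is.na(object$padj)
    if (any(object$padj[both] < object$pvalue[both] - 1e-12))
        msg <- c(msg, "padj must be >= pvalue whenever both are present")
    rng <- c(object$pvalue[!is.na(object$pvalue)],
             object$padj[!is.na(object$padj)])
    if (length(rng) && (min(rng) < 0 || max(rng) > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
}
setValidity("DETable", .validDETable)

#' MergedContrasts: inner join of two or more DETables by gene
#'
#' A \linkS4class{DFrame} keyed by \code{gene}, with per-contrast columns
#' \code{log2fc_<id>}, \code{pvalue_<id>}, \code{padj_<id>}. Produced by
#' [mergeByGene()].
#'
#' @slot contrastIds character vector of the merged contrast labels.
#' @aliases MergedContrasts-class
#' @exportClass MergedContrasts
setClass("MergedContrasts",
    contains = "DFrame",
    representation(contrastIds = "character"))

setValidity("MergedContrasts", function(object) {
    msg <- NULL
    if (length(object@contrastIds) < 2L)
        msg <- c(msg, "a MergedContrasts holds at least two contrasts")
    if (!"gene" %in% colnames(object))
        msg <- c(msg, "missing 'gene' column")
    else if (anyDuplicated(object$gene))
        msg <- c(msg, "gene symbols must be unique")
    need <- as.vector(outer(c("log2fc_", "pvalue_", "padj_"),
                            object@contrastIds, paste0))
    if (!all(need %in% colnames(object)))
        msg <- c(msg, paste0("missing per-contrast column(s): ",
                             paste(setdiff(need, colnames(object)),
                                   collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' GeneSet: a named, unordered collection of gene symbols
#'
#' @slot name single character label.
#' @slot genes character vector of unique gene symbols.
#' @aliases GeneSet-class
#' @exportClass GeneSet
setClass("GeneSet",
    representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || is.na(object@name))
        msg <- c(msg, "'name' must be a single string")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene symbols within a set must be unique")
    if (any(is.na(object@genes)) || any(!nzchar(object@genes)))
        msg <- c(msg, "gene symbols must be non-missing and non-empty")
    if (is.null(msg)) TRUE else msg
})

#' PhaseAnnotation: gene-to-cell-cycle-phase map
#'
#' Assigns each gene to exactly one of the five phases in
#' [CELL_CYCLE_PHASES].
#'
#' @slot phase named character vector; names are gene symbols, values are
#'   phase labels.
#' @aliases PhaseAnnotation-class
#' @exportClass PhaseAnnotation
setClass("PhaseAnnotation", representation(phase = "character"))

setValidity("PhaseAnnotation", function(object) {
    msg <- NULL
    ph <- object@phase
    if (is.null(names(ph)) || any(!nzchar(names(ph))))
        msg <- c(msg, "phase vector must be named by gene symbol")
    else if (anyDuplicated(names(ph)))
        msg <- c(msg, "each gene must be assigned exactly one phase")
    bad <- setdiff(unique(ph), CELL_CYCLE_PHASES)
    if (length(bad))
        msg <- c(msg, paste0("unrecognised phase label(s): ",
                             paste(bad, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' SynthConfig: parameters of the synthetic paired-knockout generator
#'
#' Describes two knockout contrasts A and B that share a regulatory program:
#' shared-program genes have true effect theta_A in contrast A and exactly
#' \code{betaTrue * theta_A} in contrast B. Each contrast additionally has a
#' private program, phase-annotated cell-cycle genes with fixed additive
#' shifts, and null genes. Observed log2 fold changes add per-gene Gaussian
#' noise whose scale is drawn log-normally around \code{sigmaNoise}.
#'
#' @slot nGenes total number of genes.
#' @slot nShared,nAOnly,nBOnly program sizes.
#' @slot muShared,tauShared mean magnitude and between-gene spread of true
#'   shared-program log2 effects in contrast A (signs are random).
#' @slot betaTrue attenuation of the shared program in contrast B, in [0,1].
#' @slot muAOnly,muBOnly mean magnitudes of the private-program effects.
#' @slot sigmaNoise median per-gene measurement noise scale (log2 units).
#' @slot sigmaSpread log-sd of the log-normal noise-scale family.
#' @slot phaseSizes named integer vector over [CELL_CYCLE_PHASES].
#' @slot phaseShiftsA,phaseShiftsB named numeric additive log2 shifts per
#'   phase in each contrast.
#' @slot eduProps,eduN named per-genotype EdU-positive proportions and cell
#'   counts.
#' @slot nReps samples per group in the count simulator.
#' @slot dispersion negative-binomial dispersion of simulated counts.
#' @slot baselineMeanLog,baselineSdLog log-normal parameters of baseline
#'   mean counts.
#' @slot contrastA,contrastB contrast labels used for the generated tables.
#' @slot seed integer seed; every generator draw flows from it.
#' @seealso [synthConfig()] for the documented defaults.
#' @aliases SynthConfig-class
#' @exportClass SynthConfig
setClass("SynthConfig",
    representation(
        nGenes = "integer", nShared = "integer",
        nAOnly = "integer", nBOnly = "integer",
        muShared = "numeric", tauShared = "numeric", betaTrue = "numeric",
        muAOnly = "numeric", muBOnly = "numeric",
        sigmaNoise = "numeric", sigmaSpread = "numeric",
        phaseSizes = "integer",
        phaseShiftsA = "numeric", phaseShiftsB = "numeric",
        eduProps = "numeric", eduN = "integer",
        nReps = "integer", dispersion = "numeric",
        baselineMeanLog = "numeric", baselineSdLog = "numeric",
        contrastA = "character", contrastB = "character",
        seed = "integer"))

setValidity("SynthConfig", function(object) {
    msg <- NULL
    pos1 <- function(x, nm) {
        if (length(x) != 1L || is.na(x))
            return(paste0("'", nm, "' must be a single non-missing value"))
        NULL
    }
    for (nm in c("nGenes", "nShared", "nAOnly", "nBOnly", "muShared",
                 "tauShared", "betaTrue", "muAOnly", "muBOnly", "sigmaNoise",
                 "sigmaSpread", "nReps", "dispersion", "baselineMeanLog",
                 "baselineSdLog", "seed"))
        msg <- c(msg, pos1(slot(object, nm), nm))
    if (length(msg)) return(msg)
    if (object@nGenes < 2L) msg <- c(msg, "'nGenes' must be >= 2")
    if (object@tauShared < 0) msg <- c(msg, "'tauShared' must be >= 0")
    if (object@sigmaNoise < 0) msg <- c(msg, "'sigmaNoise' must be >= 0")
    if (object@sigmaSpread < 0) msg <- c(msg, "'sigmaSpread' must be >= 0")
    if (object@betaTrue < 0 || object@betaTrue > 1)
        msg <- c(msg, "'betaTrue' must lie in [0, 1]")
    if (!identical(sort(names(object@phaseSizes)), sort(CELL_CYCLE_PHASES)))
        msg <- c(msg, "'phaseSizes' must be named by the five phase labels")
    for (nm in c("phaseShiftsA", "phaseShiftsB"))
        if (!identical(sort(names(slot(object, nm))),
                       sort(CELL_CYCLE_PHASES)))
            msg <- c(msg, paste0("'", nm,
                     "' must be named by the five phase labels"))
    nSig <- object@nShared + object@nAOnly + object@nBOnly +
        sum(object@phaseSizes)
    if (length(msg) == 0L && nSig > object@nGenes)
        msg <- c(msg, paste0("program and phase genes (", nSig,
                             ") exceed nGenes (", object@nGenes, ")"))
    if (any(object@eduProps < 0) || any(object@eduProps > 1))
        msg <- c(msg, "'eduProps' must lie in [0, 1]")
    if (!identical(names(object@eduProps), names(object@eduN)))
        msg <- c(msg, "'eduProps' and 'eduN' must share genotype names")
    if (any(object@eduN < 0)) msg <- c(msg, "'eduN' must be non-negative")
    if (object@nReps < 2L) msg <- c(msg, "'nReps' must be >= 2")
    if (object@dispersion < 0) msg <- c(msg, "'dispersion' must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' SynthTruth: generative ground truth of a simulated contrast pair
#'
#' A \linkS4class{DFrame} with one row per gene: program membership
#' (\code{"shared"}, \code{"a_only"}, \code{"b_only"}, \code{"phase"},
#' \code{"null"}), phase label (or \code{NA}), true effects \code{thetaA}
#' and \code{thetaB}, and the per-gene noise scales used in each contrast.
#' For shared-program genes \code{thetaB == betaTrue * thetaA} exactly.
#'
#' @slot betaTrue the generative attenuation coefficient.
#' @aliases SynthTruth-class
#' @exportClass SynthTruth
setClass("SynthTruth",
    contains = "DFrame",
    representation(betaTrue = "numeric"))

setValidity("SynthTruth", function(object) {
    msg <- NULL
    req <- c("gene", "program", "phase", "thetaA", "thetaB",
             "sigmaA", "sigmaB")
    if (!all(req %in% colnames(object)))
        return(paste0("missing column(s): ",
                      paste(setdiff(req, colnames(object)), collapse = ", ")))
    sh <- object$program == "shared"
    if (any(abs(object$thetaB[sh] -
                object@betaTrue * object$thetaA[sh]) > 1e-12))
        msg <- c(msg, "thetaB must equal betaTrue * thetaA for shared genes")
    if (is.null(msg)) TRUE else msg
})

#' OverlapTest: one-tailed hypergeometric gene-set overlap test
#'
#' @slot setAName,setBName labels of the two sets.
#' @slot nUniverse,nA,nB,nOverlap the counts entering the test.
#' @slot pvalue one-tailed (enrichment) hypergeometric p, inclusive of the
#'   observed overlap.
#' @slot padj BH-adjusted p within the requested family (\code{NA} until a
#'   family adjustment is applied).
#' @aliases OverlapTest-class
#' @exportClass OverlapTest
setClass("OverlapTest",
    representation(
        setAName = "character", setBName = "character",
        nUniverse = "integer", nA = "integer", nB = "integer",
        nOverlap = "integer", pvalue = "numeric", padj = "numeric"))

setValidity("OverlapTest", function(object) {
    msg <- NULL
    if (object@nOverlap > min(object@nA, object@nB))
        msg <- c(msg, "overlap cannot exceed either set size")
    if (max(object@nA, object@nB) > object@nUniverse)
        msg <- c(msg, "set sizes cannot exceed the universe")
    if (object@pvalue < 0 || object@pvalue > 1)
        msg <- c(msg, "pvalue must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' BootstrapNull: random-gene-set null for a Spearman correlation
#'
#' Summarises \code{nIter} Spearman correlations computed on gene sets of
#' size \code{setSize} sampled without replacement from the merged expressed
#' universe, and the standardisation of an observed correlation against
#' them.
#'
#' @slot nIter,setSize bootstrap dimensions.
#' @slot nullRhos the sampled null correlations.
#' @slot mean,sd moments of the null sample.
#' @slot rhoObs,zObs the observed correlation and its z-score.
#' @slot logP natural-log one-sided upper-tail normal p-value.
#' @slot seed the seed used for sampling.
#' @aliases BootstrapNull-class
#' @exportClass BootstrapNull
setClass("BootstrapNull",
    representation(
        nIter = "integer", setSize = "integer", nullRhos = "numeric",
        mean = "numeric", sd = "numeric", rhoObs = "numeric",
        zObs = "numeric", logP = "numeric", seed = "integer"))

setValidity("BootstrapNull", function(object) {
    msg <- NULL
    if (length(object@nullRhos) != object@nIter)
        msg <- c(msg, "nullRhos must hold nIter values")
    if (object@nIter >= 2L && !(object@sd > 0))
        msg <- c(msg, "null sd must be positive for nIter >= 2")
    z <- (object@rhoObs - mean(object@nullRhos)) / sd(object@nullRhos)
    if (abs(z - object@zObs) > 1e-12)
        msg <- c(msg, "zObs is not reproducible from the stored null sample")
    if (is.null(msg)) TRUE else msg
})

#' EpistasisFit: attenuation of one knockout's program in another contrast
#'
#' Holds the Spearman correlation of the two log2 fold-change vectors over
#' the dependent genes, and the ordinary-least-squares fit of the response
#' contrast's fold changes on the predictor contrast's: slope (the
#' attenuation coefficient), intercept, and the slope's 95\% confidence
#' interval from the t distribution on n - 2 degrees of freedom.
#'
#' @slot nGenes number of dependent genes used.
#' @slot rho,rhoP Spearman rho and the two-sided p that rho differs from 0.
#' @slot slope,intercept,slopeSE OLS estimates and the slope standard error.
#' @slot ci95 numeric length-2 confidence bounds for the slope.
#' @slot responseContrast,predictorContrast contrast labels of the fit.
#' @aliases EpistasisFit-class
#' @exportClass EpistasisFit
setClass("EpistasisFit",
    representation(
        nGenes = "integer", rho = "numeric", rhoP = "numeric",
        slope = "numeric", intercept = "numeric", slopeSE = "numeric",
        ci95 = "numeric", responseContrast = "character",
        predictorContrast = "character"))

setValidity("EpistasisFit", function(object) {
    msg <- NULL
    if (length(object@ci95) != 2L)
        msg <- c(msg, "ci95 must have length 2")
    else if (!(object@ci95[1L] <= object@slope &&
               object@slope <= object@ci95[2L]))
        msg <- c(msg, "slope must lie inside its confidence interval")
    if (is.finite(object@rho) && abs(object@rho) > 1 + 1e-12)
        msg <- c(msg, "|rho| cannot exceed 1")
    if (is.null(msg)) TRUE else msg
})
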