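## Constructors, accessors and show() methods.

#' Construct a DETable
#'
#' @param gene character vector of unique gene symbols.
#' @param log2fc numeric log2 fold changes, oriented wild-type/knockout.
#' @param pvalue,padj raw and adjusted p-values in \code{[0, 1]}; \code{NA}
#'   marks a missing value.
#' @param expressed logical; defaults to \code{TRUE} for all genes.
#' @param contrastId single character label for the contrast.
#' @return A [DETable-class] object.
#' @examples
#' tab <- DETable(gene = c("Ccna2", "Stra8", "Meiosin"),
#'                log2fc = c(-1.2, 0.4, 2.1),
#'                pvalue = c(1e-4, 0.2, 1e-6),
#'                padj   = c(1e-3, 0.35, 1e-5),
#'                contrastId = "WT_vs_MeiocKO")
#' tab
#' @export
DETable <- function(gene, log2fc, pvalue = NA_real_, padj = NA_real_,
                    expressed = TRUE, contrastId = "contrast") {
    n <- length(gene)
    df <- DataFrame(gene = as.character(gene),
                    log2fc = as.numeric(log2fc),
                    pvalue = rep_len(as.numeric(pvalue), n),
                    padj = rep_len(as.numeric(padj), n),
                    expressed = rep_len(as.logical(expressed), n))
    new("DETable", df, contrastId = as.character(contrastId))
}

#' @rdname DETable
#' @export
setMethod("contrastId", "DETable", function(x) x@contrastId)

#' @rdname MergedContrasts-class
#' @export
setMethod("contrastIds", "MergedContrasts", function(x) x@contrastIds)

setMethod("show", "DETable", function(object) {
    cat("DETable for contrast ", sQuote(object@contrastId), ": ",
        nrow(object), " genes (", sum(object$expressed), " expressed, ",
        sum(!is.na(object$padj) & object$padj < 0.05),
        " with padj < 0.05)\n", sep = "")
    callNextMethod()
})

setMethod("show", "MergedContrasts", function(object) {
    cat("MergedContrasts over ", nrow(object), " shared genes; contrasts: ",
        paste(sQuote(object@contrastIds), collapse = ", "), "\n", sep = "")
    callNextMethod()
})

#' Construct a GeneSet
#'
#' @param name single character label.
#' @param genes character vector of gene symbols; duplicates are removed.
#' @return A [GeneSet-class] object.
#' @examples
#' gs <- GeneSet("cell_cycle_regulators", c("Ccna2", "Ccnb1", "Cdk1"))
#' geneIds(gs)
#' @export
GeneSet <- function(name, genes) {
    new("GeneSet", name = as.character(name),
        genes = unique(as.character(genes)))
}

#' @rdname GeneSet
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)

#' @rdname GeneSet
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname GeneSet
#' @export
setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet ", sQuote(object@name), ": ", length(object@genes),
        " genes\n", sep = "")
})

#' Construct a PhaseAnnotation
#'
#' @param genes character vector of gene symbols.
#' @param phases character vector of phase labels, one of
#'   [CELL_CYCLE_PHASES], parallel to \code{genes}.
#' @return A [PhaseAnnotation-class] object.
#' @examples
#' ann <- PhaseAnnotation(c("Mcm2", "Pcna", "Ccnb1"), c("G1/S", "S", "M"))
#' phaseOf(ann)
#' @export
PhaseAnnotation <- function(genes, phases) {
    stopifnot(length(genes) == length(phases))
    ph <- as.character(phases)
    names(ph) <- as.character(genes)
    new("PhaseAnnotation", phase = ph)
}

#' @rdname PhaseAnnotation
#' @export
setMethod("phaseOf", "PhaseAnnotation", function(x) x@phase)

#' @rdname PhaseAnnotation
#' @export
setMethod("geneIds", "PhaseAnnotation", function(x) names(x@phase))

#' @rdname PhaseAnnotation
#' @export
setMethod("length", "PhaseAnnotation", function(x) length(x@phase))

setMethod("show", "PhaseAnnotation", function(object) {
    tab <- table(factor(object@phase, levels = CELL_CYCLE_PHASES))
    cat("PhaseAnnotation over", length(object@phase), "genes:\n")
    print(tab)
})

#' @rdname SynthTruth-class
#' @export
setMethod("betaTrue", "SynthTruth", function(x) x@betaTrue)

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig: ", object@nGenes, " genes (shared ", object@nShared,
        ", A-only ", object@nAOnly, ", B-only ", object@nBOnly,
        ", phase ", sum(object@phaseSizes), ")\n",
        "  betaTrue = ", object@betaTrue,
        ", muShared = ", object@muShared,
        ", tauShared = ", object@tauShared,
        ", sigmaNoise = ", object@sigmaNoise, "\n",
        "  seed = ", object@seed, "\n", sep = "")
})

setMethod("show", "SynthTruth", function(object) {
    cat("SynthTruth (betaTrue = ", object@betaTrue, "): ",
        nrow(object), " genes\n", sep = "")
    print(table(object$program))
})

setMethod("show", "OverlapTest", function(object) {
    cat("OverlapTest: ", sQuote(object@setAName), " (n=", object@nA,
        ") vs ", sQuote(object@setBName), " (n=", object@nB, ")\n",
        "  overlap ", object@nOverlap, " of universe ", object@nUniverse,
        "; one-tailed hypergeometric p = ", format(object@pvalue, digits = 4),
        if (!is.na(object@padj))
            paste0(", padj = ", format(object@padj, digits = 4)) else "",
        "\n", sep = "")
})

setMethod("show", "BootstrapNull", function(object) {
    cat("BootstrapNull: ", object@nIter, " random gene sets of size ",
        object@setSize, " (seed ", object@seed, ")\n",
        "  null mean = ", format(object@mean, digits = 4),
        ", sd = ", format(object@sd, digits = 4), "\n",
        "  observed rho = ", format(object@rhoObs, digits = 4),
        ", z = ", format(object@zObs, digits = 4),
        ", ln(p) = ", format(object@logP, digits = 4), "\n", sep = "")
})

setMethod("show", "EpistasisFit", function(object) {
    cat("EpistasisFit: ", object@responseContrast, " ~ ",
        object@predictorContrast, " over ", object@nGenes,
        " dependent genes\n",
        "  slope = ", format(object@slope, digits = 3),
        " (95% CI ", format(object@ci95[1L], digits = 3), "-",
        format(object@ci95[2L], digits = 3),
        "), intercept = ", format(object@intercept, digits = 3), "\n",
        "  Spearman rho = ", format(object@rho, digits = 3),
        ", p = ", format(object@rhoP, digits = 4), "\n", sep = "")
})
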