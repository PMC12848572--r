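## Synthetic paired-knockout generator with ground truth.

#' Default synthetic configuration
#'
#' Builds a [SynthConfig-class]. The defaults describe two knockout
#' contrasts, A and B, whose shared regulatory program (600 genes with
#' signed true log2 effects of magnitude ~ Normal(1.0, 0.4) in A) reappears
#' in B attenuated by \code{betaTrue = 0.43}; each contrast also has a
#' 400-gene private program of the same strength, 320 phase-annotated
#' cell-cycle genes with fixed additive shifts (contrast A: +0.5 in G1/S and
#' S only; contrast B: -0.5 in all five phases), and null genes. Observed
#' log2 fold changes add Normal(0, sigma_g) noise with sigma_g drawn
#' log-normally (median \code{sigmaNoise = 0.3}, log-sd
#' \code{sigmaSpread = 0.4}) per gene and contrast, so adjusted-p selection
#' of dependent genes is nontrivial and heteroskedastic, as in real
#' differential-expression output.
#'
#' EdU labeling-index defaults give the wild-type group a positive
#' proportion of 0.045 over 7703 cells; the knockout groups are synthetic
#' plausible values (a meiotic-initiation knockout slightly below wild type,
#' a mitotic-arrest knockout and double knockout well above it).
#'
#' @param nGenes,nShared,nAOnly,nBOnly,muShared,tauShared,betaTrue numeric;
#'   see [SynthConfig-class].
#' @param muAOnly,muBOnly,sigmaNoise,sigmaSpread numeric; see
#'   [SynthConfig-class].
#' @param phaseSizes,phaseShiftsA,phaseShiftsB named vectors over
#'   [CELL_CYCLE_PHASES].
#' @param eduProps,eduN named per-genotype proportions and cell counts.
#' @param nReps,dispersion,baselineMeanLog,baselineSdLog count-simulator
#'   parameters.
#' @param contrastA,contrastB contrast labels.
#' @param seed integer seed driving all generator randomness.
#' @return A validated [SynthConfig-class].
#' @examples
#' cfg <- synthConfig(seed = 11L)
#' cfg
#' @export
synthConfig <- function(nGenes = 12000L, nShared = 600L,
                        nAOnly = 400L, nBOnly = 400L,
                        muShared = 1.0, tauShared = 0.4, betaTrue = 0.43,
                        muAOnly = 1.0, muBOnly = 1.0,
                        sigmaNoise = 0.3, sigmaSpread = 0.4,
                        phaseSizes = c("G1/S" = 60L, "S" = 60L, "G2" = 70L,
                                       "M" = 80L, "M/G1" = 50L),
                        phaseShiftsA = c("G1/S" = 0.5, "S" = 0.5, "G2" = 0,
                                         "M" = 0, "M/G1" = 0),
                        phaseShiftsB = c("G1/S" = -0.5, "S" = -0.5,
                                         "G2" = -0.5, "M" = -0.5,
                                         "M/G1" = -0.5),
                        eduProps = c(WT = 0.045, KO_A = 0.030,
                                     KO_B = 0.150, dKO = 0.170),
                        eduN = c(WT = 7703L, KO_A = 6000L,
                                 KO_B = 3500L, dKO = 3600L),
                        nReps = 3L, dispersion = 0.05,
                        baselineMeanLog = log(100), baselineSdLog = 1.5,
                        contrastA = "contrastA", contrastB = "contrastB",
                        seed = 20251L) {
    new("SynthConfig",
        nGenes = as.integer(nGenes), nShared = as.integer(nShared),
        nAOnly = as.integer(nAOnly), nBOnly = as.integer(nBOnly),
        muShared = muShared, tauShared = tauShared, betaTrue = betaTrue,
        muAOnly = muAOnly, muBOnly = muBOnly,
        sigmaNoise = sigmaNoise, sigmaSpread = sigmaSpread,
        phaseSizes = setNames(as.integer(phaseSizes), names(phaseSizes)),
        phaseShiftsA = phaseShiftsA, phaseShiftsB = phaseShiftsB,
        eduProps = eduProps, eduN = setNames(as.integer(eduN), names(eduN)),
        nReps = as.integer(nReps), dispersion = dispersion,
        baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
        contrastA = contrastA, contrastB = contrastB,
        seed = as.integer(seed))
}

## True per-gene effects and memberships, deterministic given config seed.
.drawTruth <- function(config) {
    n <- config@nGenes
    phases <- rep(names(config@phaseSizes), config@phaseSizes)
    nPhase <- length(phases)
    program <- rep("null", n)
    program[seq_len(config@nShared)] <- "shared"
    program[config@nShared + seq_len(config@nAOnly)] <- "a_only"
    program[config@nShared + config@nAOnly + seq_len(config@nBOnly)] <-
        "b_only"
    iPhase <- config@nShared + config@nAOnly + config@nBOnly +
        seq_len(nPhase)
    program[iPhase] <- "phase"
    phase <- rep(NA_character_, n)
    phase[iPhase] <- phases
    signedEffect <- function(k, mu, tau)
        sample(c(-1, 1), k, replace = TRUE) * rnorm(k, mu, tau)
    thetaA <- numeric(n)
    thetaB <- numeric(n)
    sh <- which(program == "shared")
    thetaA[sh] <- signedEffect(length(sh), config@muShared,
                               config@tauShared)
    thetaB[sh] <- config@betaTrue * thetaA[sh]
    ao <- which(program == "a_only")
    thetaA[ao] <- signedEffect(length(ao), config@muAOnly, config@tauShared)
    bo <- which(program == "b_only")
    thetaB[bo] <- signedEffect(length(bo), config@muBOnly, config@tauShared)
    thetaA[iPhase] <- config@phaseShiftsA[phases]
    thetaB[iPhase] <- config@phaseShiftsB[phases]
    gene <- sprintf("g%05d", seq_len(n))
    sigma <- function() rlnorm(n, meanlog = log(config@sigmaNoise),
                               sdlog = config@sigmaSpread)
    sigmaA <- if (config@sigmaNoise > 0) sigma() else numeric(n)
    sigmaB <- if (config@sigmaNoise > 0) sigma() else numeric(n)
    new("SynthTruth",
        DataFrame(gene = gene, program = program, phase = phase,
                  thetaA = thetaA, thetaB = thetaB,
                  sigmaA = sigmaA, sigmaB = sigmaB),
        betaTrue = config@betaTrue)
}

## Observed table for one contrast from truth columns.
.observeContrast <- function(gene, theta, sigma, contrastId) {
    n <- length(theta)
    if (length(sigma) && any(sigma > 0)) {
        lfc <- theta + rnorm(n, 0, sigma)
        p <- 2 * pnorm(-abs(lfc / sigma))
    } else {
        ## noiseless limit: observed equals truth, p degenerates
        lfc <- theta
        p <- ifelse(theta == 0, 1, 0)
    }
    DETable(gene = gene, log2fc = lfc, pvalue = p, padj = bhAdjust(p),
            expressed = TRUE, contrastId = contrastId)
}

#' Generate a synthetic pair of knockout contrasts with ground truth
#'
#' Draws true effects per [SynthConfig-class], adds per-gene Gaussian noise
#' with log-normally distributed scales, converts each observed fold change
#' to a two-sided normal-tail p-value against its own noise scale, and
#' BH-adjusts within each table. Deterministic given \code{config@seed}.
#'
#' @param config a [SynthConfig-class].
#' @return A list with elements \code{tableA} and \code{tableB}
#'   ([DETable-class]) and \code{truth} ([SynthTruth-class]).
#' @examples
#' sim <- generateContrastPair(synthConfig(nGenes = 2000L, nShared = 100L,
#'                                         nAOnly = 50L, nBOnly = 50L,
#'                                         seed = 5L))
#' sim$truth
#' @export
generateContrastPair <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    withSeed(config@seed, {
        truth <- .drawTruth(config)
        tableA <- .observeContrast(truth$gene, truth$thetaA, truth$sigmaA,
                                   config@contrastA)
        tableB <- .observeContrast(truth$gene, truth$thetaB, truth$sigmaB,
                                   config@contrastB)
        list(tableA = tableA, tableB = tableB, truth = truth)
    })
}

#' Generate negative-binomial counts encoding one contrast's true effects
#'
#' Simulates a genes-by-samples count matrix for a two-group (wild-type vs
#' knockout) design. Baseline mean counts are log-normal across genes; the
#' wild-type group mean is the baseline scaled by \code{2^theta}, where
#' theta is the contrast's true effect from the same truth draw as
#' [generateContrastPair()] (log2 fold change oriented wild-type/knockout).
#' Counts are negative binomial with dispersion \code{config@dispersion}
#' (Poisson when 0). Deterministic given \code{config@seed}.
#'
#' @param config a [SynthConfig-class].
#' @param contrast \code{"A"} or \code{"B"}: which contrast's effects the
#'   group means encode.
#' @return A \linkS4class{SummarizedExperiment} with assay \code{"counts"}
#'   and \code{colData(x)$group} in \code{c("WT", "KO")}.
#' @export
generateCounts <- function(config, contrast = c("A", "B")) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    contrast <- match.arg(contrast)
    withSeed(config@seed, {
        truth <- .drawTruth(config)
        theta <- if (contrast == "A") truth$thetaA else truth$thetaB
        n <- config@nGenes
        base <- rlnorm(n, config@baselineMeanLog, config@baselineSdLog)
        muWT <- base * 2^theta
        muKO <- base
        nr <- config@nReps
        draw <- function(mu) {
            if (config@dispersion > 0)
                matrix(rnbinom(n * nr, mu = mu,
                               size = 1 / config@dispersion), nrow = n)
            else matrix(stats::rpois(n * nr, lambda = mu), nrow = n)
        }
        m <- cbind(draw(muWT), draw(muKO))
        rownames(m) <- truth$gene
        colnames(m) <- c(paste0("WT_", seq_len(nr)),
                         paste0("KO_", seq_len(nr)))
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = m),
            colData = DataFrame(group = rep(c("WT", "KO"), each = nr),
                                row.names = colnames(m)))
    })
}

#' Naive two-group differential expression on simulated counts
#'
#' A deliberately simple stand-in estimator used only on generator output:
#' log2 fold change is the difference of group means of
#' \code{log2(counts-per-million + 0.5)} (group 1 minus group 2), the
#' p-value comes from Welch's unequal-variance t-test per gene, and adjusted
#' p-values from [bhAdjust()]. Genes whose per-group values are constant and
#' equal across groups get p = 1.
#'
#' @param x a \linkS4class{SummarizedExperiment} with a \code{"counts"}
#'   assay, or a counts matrix.
#' @param groups character/factor of length \code{ncol(x)} with exactly two
#'   levels; defaults to \code{colData(x)$group}. The first level (in order
#'   of first appearance) is group 1, so with the [generateCounts()] layout
#'   the orientation is wild-type over knockout.
#' @param contrastId label for the resulting [DETable-class].
#' @return A [DETable-class].
#' @export
estimateDENaive <- function(x, groups = NULL, contrastId = "naive") {
    m <- if (is(x, "SummarizedExperiment")) {
        if (is.null(groups))
            groups <- SummarizedExperiment::colData(x)$group
        SummarizedExperiment::assays(x)[["counts"]]
    } else as.matrix(x)
    if (is.null(groups)) stop("'groups' is required")
    groups <- as.character(groups)
    lev <- unique(groups)
    if (length(lev) != 2L) stop("exactly two groups are required")
    i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
    if (length(i1) < 2L || length(i2) < 2L)
        stop("each group needs at least 2 samples")
    libSize <- colSums(m)
    logcpm <- log2(sweep(m, 2L, libSize / 1e6, "/") + 0.5)
    m1 <- rowMeans(logcpm[, i1, drop = FALSE])
    m2 <- rowMeans(logcpm[, i2, drop = FALSE])
    v1 <- apply(logcpm[, i1, drop = FALSE], 1L, var)
    v2 <- apply(logcpm[, i2, drop = FALSE], 1L, var)
    lfc <- m1 - m2
    se2 <- v1 / length(i1) + v2 / length(i2)
    p <- numeric(nrow(m))
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
    if (any(!degenerate)) {
        tstat <- lfc[!degenerate] / sqrt(se2[!degenerate])
        df <- se2[!degenerate]^2 /
            (v1[!degenerate]^2 / (length(i1)^2 * (length(i1) - 1L)) +
             v2[!degenerate]^2 / (length(i2)^2 * (length(i2) - 1L)))
        p[!degenerate] <- 2 * stats::pt(-abs(tstat), df)
    }
    DETable(gene = rownames(m), log2fc = lfc, pvalue = p,
            padj = bhAdjust(p), expressed = TRUE, contrastId = contrastId)
}

#' Generate per-genotype EdU labeling counts
#'
#' EdU-positive counts are binomial draws per genotype with the configured
#' proportions and totals. Deterministic given \code{config@seed}.
#'
#' @param config a [SynthConfig-class].
#' @return A data.frame with columns \code{group}, \code{positive},
#'   \code{negative}.
#' @export
generateEduCounts <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    withSeed(config@seed, {
        pos <- rbinom(length(config@eduN), size = config@eduN,
                      prob = config@eduProps)
        data.frame(group = names(config@eduN), positive = pos,
                   negative = config@eduN - pos, row.names = NULL,
                   stringsAsFactors = FALSE)
    })
}

#' Phase annotation of a truth object
#'
#' @param truth a [SynthTruth-class].
#' @return A [PhaseAnnotation-class] over the generator's phase genes.
#' @export
truthPhaseAnnotation <- function(truth) {
    stopifnot(is(truth, "SynthTruth"))
    i <- which(truth$program == "phase")
    PhaseAnnotation(truth$gene[i], truth$phase[i])
}

#' Write a complete synthetic data bundle to a directory
#'
#' Materialises everything the downstream analyses consume: the two DE
#' tables, a TPM-scaled count matrix for contrast A, the phase annotation,
#' the EdU count table and the truth table, all tab-delimited.
#'
#' @param config a [SynthConfig-class].
#' @param dir output directory, created if needed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeSyntheticData <- function(config, dir) {
    stopifnot(is(config, "SynthConfig"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sim <- generateContrastPair(config)
    counts <- generateCounts(config, contrast = "A")
    m <- SummarizedExperiment::assays(counts)[["counts"]]
    tpm <- sweep(m, 2L, colSums(m) / 1e6, "/")
    paths <- c(
        tableA = file.path(dir, paste0(config@contrastA, ".tsv")),
        tableB = file.path(dir, paste0(config@contrastB, ".tsv")),
        tpm = file.path(dir, "tpm_matrix.tsv"),
        phases = file.path(dir, "phase_annotation.tsv"),
        edu = file.path(dir, "edu_counts.tsv"),
        truth = file.path(dir, "truth.tsv"))
    writeDETable(sim$tableA, paths[["tableA"]])
    writeDETable(sim$tableB, paths[["tableB"]])
    write.table(data.frame(gene = rownames(tpm), tpm, check.names = FALSE),
                paths[["tpm"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writePhaseAnnotation(truthPhaseAnnotation(sim$truth), paths[["phases"]])
    write.table(generateEduCounts(config), paths[["edu"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    tr <- as.data.frame(sim$truth)
    tr$betaTrue <- betaTrue(sim$truth)
    write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(paths)
}
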