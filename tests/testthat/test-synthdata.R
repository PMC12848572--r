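test_that("the generator is deterministic given its seed", {
    cfg <- smallConfig(seed = 11L)
    s1 <- generateContrastPair(cfg)
    s2 <- generateContrastPair(cfg)
    expect_identical(as.data.frame(s1$tableA), as.data.frame(s2$tableA))
    expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
    s3 <- generateContrastPair(smallConfig(seed = 12L))
    expect_false(identical(s1$tableA$log2fc, s3$tableA$log2fc))

    c1 <- generateCounts(cfg)
    c2 <- generateCounts(cfg)
    expect_identical(SummarizedExperiment::assay(c1),
                     SummarizedExperiment::assay(c2))

    e1 <- generateEduCounts(cfg)
    expect_identical(e1, generateEduCounts(cfg))
})

test_that("generator randomness does not disturb the caller's RNG stream", {
    set.seed(99)
    before <- .Random.seed
    invisible(generateContrastPair(smallConfig(seed = 1L)))
    expect_identical(.Random.seed, before)
})

test_that("truth encodes the attenuated shared program exactly", {
    sim <- generateContrastPair(smallConfig(seed = 3L))
    tr <- sim$truth
    sh <- tr$program == "shared"
    expect_equal(tr$thetaB[sh], betaTrue(tr) * tr$thetaA[sh],
                 tolerance = 1e-12)
    expect_true(all(tr$thetaB[tr$program == "a_only"] == 0))
    expect_true(all(tr$thetaA[tr$program == "b_only"] == 0))
    expect_true(all(tr$thetaA[tr$program == "null"] == 0))
    ## least squares on the noiseless truth recovers betaTrue exactly
    fit <- lm(tr$thetaB[sh] ~ tr$thetaA[sh])
    expect_equal(unname(coef(fit)), c(0, betaTrue(tr)), tolerance = 1e-09)
})

test_that("the noiseless limit collapses observation onto truth", {
    cfg <- smallConfig(seed = 5L, sigmaNoise = 0, betaTrue = 1)
    sim <- generateContrastPair(cfg)
    sh <- sim$truth$program == "shared"
    expect_identical(sim$tableA$log2fc[sh], sim$tableB$log2fc[sh])
    expect_true(all(sim$tableA$pvalue[sim$truth$thetaA == 0] == 1))
    expect_true(all(sim$tableA$pvalue[sim$truth$thetaA != 0] == 0))

    cfg0 <- smallConfig(seed = 5L, sigmaNoise = 0, betaTrue = 0)
    sim0 <- generateContrastPair(cfg0)
    sh0 <- sim0$truth$program == "shared"
    expect_true(all(sim0$tableB$log2fc[sh0] == 0))
})

test_that("null-gene p-values are uniform", {
    sim <- generateContrastPair(synthConfig(seed = 201L))
    p <- sim$tableA$pvalue[sim$truth$program == "null"]
    expect_gt(length(p), 2000L)
    ks <- suppressWarnings(ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("simulated counts have the configured mean and dispersion shape", {
    base <- synthConfig(nGenes = 300L, nShared = 0L, nAOnly = 0L,
                        nBOnly = 0L,
                        phaseSizes = c("G1/S" = 0L, "S" = 0L, "G2" = 0L,
                                       "M" = 0L, "M/G1" = 0L),
                        phaseShiftsA = c("G1/S" = 0, "S" = 0, "G2" = 0,
                                         "M" = 0, "M/G1" = 0),
                        nReps = 50L, baselineSdLog = 0.3, seed = 31L)
    ## zero effects: the two group means agree as replication grows
    se <- generateCounts(base)
    m <- SummarizedExperiment::assay(se)
    g <- SummarizedExperiment::colData(se)$group
    ratio <- rowMeans(m[, g == "WT"]) / rowMeans(m[, g == "KO"])
    expect_lt(abs(mean(ratio) - 1), 0.05)

    ## small dispersion approaches Poisson variance (var/mean -> 1)
    nearPois <- synthConfig(nGenes = 300L, nShared = 0L, nAOnly = 0L,
                            nBOnly = 0L,
                            phaseSizes = c("G1/S" = 0L, "S" = 0L,
                                           "G2" = 0L, "M" = 0L,
                                           "M/G1" = 0L),
                            phaseShiftsA = c("G1/S" = 0, "S" = 0,
                                             "G2" = 0, "M" = 0,
                                             "M/G1" = 0),
                            nReps = 100L, dispersion = 1e-04,
                            baselineMeanLog = log(50), baselineSdLog = 0,
                            seed = 32L)
    m2 <- SummarizedExperiment::assay(generateCounts(nearPois))
    vm <- apply(m2, 1L, var) / rowMeans(m2)
    expect_lt(abs(median(vm) - 1), 0.15)

    ## large dispersion is visibly super-Poisson
    overdisp <- synthConfig(nGenes = 300L, nShared = 0L, nAOnly = 0L,
                            nBOnly = 0L,
                            phaseSizes = c("G1/S" = 0L, "S" = 0L,
                                           "G2" = 0L, "M" = 0L,
                                           "M/G1" = 0L),
                            phaseShiftsA = c("G1/S" = 0, "S" = 0,
                                             "G2" = 0, "M" = 0,
                                             "M/G1" = 0),
                            nReps = 100L, dispersion = 0.5,
                            baselineMeanLog = log(50), baselineSdLog = 0,
                            seed = 33L)
    m3 <- SummarizedExperiment::assay(generateCounts(overdisp))
    vm3 <- apply(m3, 1L, var) / rowMeans(m3)
    expect_gt(median(vm3), 5)
})

test_that("the naive DE estimator behaves on degenerate and hand-built input", {
    ## identical constant columns in both groups: log2fc 0, p 1 per gene
    m0 <- rbind(g1 = rep(10, 4), g2 = rep(40, 4))
    colnames(m0) <- c("w1", "w2", "k1", "k2")
    groups <- c("WT", "WT", "KO", "KO")
    tab0 <- estimateDENaive(m0, groups)
    expect_equal(tab0$log2fc, c(0, 0))
    expect_equal(tab0$pvalue, c(1, 1))

    ## hand-checked two-gene, four-sample case against Welch's t-test
    m <- rbind(up = c(60, 68, 21, 19), down = c(40, 32, 79, 81))
    colnames(m) <- colnames(m0)
    tab <- estimateDENaive(m, groups)
    logcpm <- log2(sweep(m, 2, colSums(m) / 1e6, "/") + 0.5)
    for (i in 1:2) {
        expect_equal(tab$log2fc[i],
                     mean(logcpm[i, 1:2]) - mean(logcpm[i, 3:4]),
                     tolerance = 1e-12)
        oracle <- t.test(logcpm[i, 1:2], logcpm[i, 3:4])$p.value
        expect_equal(tab$pvalue[i], oracle, tolerance = 1e-12)
    }
    expect_gt(tab$log2fc[1L], 0)
    expect_lt(tab$log2fc[2L], 0)
    expect_error(estimateDENaive(m, c("WT", "KO", "KO", "KO")),
                 "at least 2")
})

test_that("the naive DE estimator recovers strong effect signs", {
    cfg <- synthConfig(nGenes = 800L, nShared = 100L, nAOnly = 0L,
                       nBOnly = 0L, muShared = 2, tauShared = 0.2,
                       phaseSizes = c("G1/S" = 0L, "S" = 0L, "G2" = 0L,
                                      "M" = 0L, "M/G1" = 0L),
                       nReps = 4L, seed = 41L)
    se <- generateCounts(cfg)
    tab <- estimateDENaive(se, contrastId = "A")
    truth <- generateContrastPair(cfg)$truth
    sh <- truth$program == "shared"
    agree <- sign(tab$log2fc[sh]) == sign(truth$thetaA[sh])
    expect_gte(mean(agree), 0.95)
})

test_that("EdU counts are binomial draws with the configured proportions", {
    cfg <- smallConfig(seed = 55L,
                       eduProps = c(WT = 0.045, KO = 0),
                       eduN = c(WT = 7703L, KO = 500L))
    tab <- generateEduCounts(cfg)
    expect_identical(tab$positive[tab$group == "KO"], 0L)
    pHat <- tab$positive[tab$group == "WT"] / 7703
    se <- sqrt(0.045 * 0.955 / 7703)
    expect_lt(abs(pHat - 0.045), 3 * se)
    expect_equal(tab$positive + tab$negative, unname(c(7703L, 500L)))
})

test_that("invalid configurations are rejected with the violated constraint", {
    expect_error(synthConfig(nGenes = 100L, nShared = 600L),
                 "exceed nGenes")
    expect_error(synthConfig(betaTrue = 1.5), "betaTrue")
    expect_error(synthConfig(eduProps = c(WT = 1.2), eduN = c(WT = 10L)),
                 "eduProps")
    expect_error(synthConfig(phaseSizes = c(G1 = 5L)), "phase")
})

test_that("a written synthetic bundle drives the full pipeline from disk", {
    dir <- withr::local_tempdir()
    cfg <- smallConfig(seed = 77L)
    paths <- writeSyntheticData(cfg, dir)
    expect_true(all(file.exists(paths)))

    a <- readDETable(paths[["tableA"]], "contrastA")
    b <- readDETable(paths[["tableB"]], "contrastB")
    merged <- mergeByGene(list(a, b))
    expect_equal(nrow(merged), 2000L)

    ann <- readPhaseAnnotation(paths[["phases"]])
    scores <- phaseScoreTest(percentileRanks(b), ann)
    expect_equal(nrow(scores), 5L)

    fit <- fitAttenuation(merged)
    expect_s4_class(fit, "EpistasisFit")

    se <- readTpmMatrix(paths[["tpm"]])
    expect_gt(length(geneIds(filterExpressed(se, 1, 3L))), 0L)

    edu <- read.delim(paths[["edu"]])
    expect_s3_class(chisqHomogeneity(edu)$posthoc, "data.frame")

    truth <- read.delim(paths[["truth"]])
    expect_equal(unique(truth$betaTrue), 0.43)
})
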