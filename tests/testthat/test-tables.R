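test_that("DETable round-trips through write/read field-for-field", {
    tab <- makeDETable(n = 25L, contrastId = "WT_vs_KO")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDETable(tab, path)
    back <- readDETable(path, contrastId = "WT_vs_KO")
    expect_s4_class(back, "DETable")
    expect_identical(back$gene, tab$gene)
    expect_equal(back$log2fc, tab$log2fc)
    expect_equal(back$pvalue, tab$pvalue)
    expect_equal(back$padj, tab$padj)
    expect_identical(back$expressed, tab$expressed)
    expect_identical(contrastId(back), "WT_vs_KO")
})

test_that("readDETable rejects malformed input and tolerates missing padj", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\tlog2fc\tpvalue\tpadj",
                 "Ccna2\t1.0\t0.01\t0.02",
                 "Ccna2\t-0.5\t0.2\t0.3"), path)
    expect_error(readDETable(path, "x"), "Ccna2")

    writeLines(c("gene\tlog2fc\tpvalue\tpadj",
                 "Ccna2\t1.0\t0.01\t0.02",
                 "Stra8\toops\t0.2\t0.3"), path)
    expect_error(readDETable(path, "x"), "row 2")

    writeLines(c("gene\tlog2fc\tpvalue",
                 "Ccna2\t1.0\t0.01",
                 "Stra8\t-0.5\t0.2"), path)
    expect_warning(tab <- readDETable(path, "x"), "padj")
    expect_true(all(is.na(tab$padj)))
    expect_equal(nrow(tab), 2L)
})

test_that("DETable validity enforces its invariants", {
    expect_error(DETable(c("a", "a"), c(1, 2), contrastId = "x"),
                 "duplicate")
    expect_error(DETable("a", NA_real_, expressed = TRUE,
                         contrastId = "x"), "finite")
    expect_error(DETable("a", 1, pvalue = 0.5, padj = 0.1,
                         contrastId = "x"), "padj")
    ## unexpressed genes may carry non-finite log2fc
    expect_s4_class(DETable(c("a", "b"), c(1, NA), expressed = c(TRUE, FALSE),
                            contrastId = "x"), "DETable")
})

test_that("filterExpressed applies an inclusive TPM >= threshold rule", {
    m <- rbind(kept = c(1.0, 1.0, 1.0, 0, 0, 0),
               dropped = c(1.2, 0.5, 3.0, 0, 0, 0),
               zero = rep(0, 6))
    got <- geneIds(filterExpressed(m, minTpm = 1, minSamples = 3L))
    expect_identical(got, "kept")
    expect_identical(geneIds(filterExpressed(m, minTpm = 1,
                                             minSamples = 1L)),
                     c("kept", "dropped"))
    expect_error(filterExpressed(matrix(numeric(0), 0, 0)), "empty")
    expect_error(filterExpressed(m, minTpm = 1, minSamples = 7L),
                 "minSamples")
})

test_that("mergeByGene inner-joins on gene symbols", {
    u <- sprintf("g%03d", 1:100)
    a <- DETable(u, rnorm(100), 0.5, 0.6, contrastId = "A")
    b <- DETable(u, rnorm(100), 0.5, 0.6, contrastId = "B")
    m <- mergeByGene(list(a, b))
    expect_equal(nrow(m), 100L)
    expect_setequal(contrastIds(m), c("A", "B"))

    b2 <- DETable(sprintf("g%03d", 41:120), rnorm(80), 0.5, 0.6,
                  contrastId = "B")
    expect_equal(nrow(mergeByGene(list(a, b2))), 60L)

    c2 <- DETable(sprintf("h%03d", 1:50), rnorm(50), 0.5, 0.6,
                  contrastId = "C")
    expect_error(mergeByGene(list(a, c2)), "shared")
})

test_that("mergeByGene is associative up to column order", {
    u <- sprintf("g%03d", 1:50)
    tabs <- lapply(c("A", "B", "C"), function(id)
        DETable(sample(u), rnorm(50), runif(50, 0, 0.5),
                runif(50, 0.5, 1), contrastId = id))
    m1 <- mergeByGene(tabs)
    m2 <- mergeByGene(tabs[c(2, 3, 1)])
    m2 <- m2[match(m1$gene, m2$gene), colnames(m1)]
    expect_equal(as.data.frame(m1), as.data.frame(m2),
                 ignore_attr = TRUE)
})

test_that("regulated sets follow the sign/padj definition", {
    tab <- DETable(gene = c("up", "down", "na_padj", "weak"),
                   log2fc = c(0.5, -0.5, 0.5, 0.2),
                   pvalue = c(0.01, 0.01, 0.01, 0.5),
                   padj = c(0.04, 0.04, NA, 0.9),
                   contrastId = "X")
    sets <- defineRegulatedSets(tab, alpha = 0.05)
    expect_identical(geneIds(sets$upregulated), "up")
    expect_identical(geneIds(sets$downregulated), "down")
    expect_setequal(geneIds(sets$dependent), c("up", "down"))
})

test_that("up/down sets are disjoint and bounded by the significant count", {
    for (seed in 1:5) {
        tab <- makeDETable(n = 200L, seed = seed)
        sets <- defineRegulatedSets(tab, alpha = 0.3)
        up <- geneIds(sets$upregulated)
        down <- geneIds(sets$downregulated)
        expect_length(intersect(up, down), 0L)
        nSig <- sum(!is.na(tab$padj) & tab$padj < 0.3)
        expect_lte(length(up) + length(down), nSig)
    }
})

test_that("bhAdjust matches the hand step-up oracle and p.adjust edge cases", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
                 c(0.04, 0.04, 0.04, 0.04))
    expect_equal(bhAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(42)
    for (i in 1:10) {
        p <- runif(sample(2:40, 1))
        q <- bhAdjust(p)
        expect_equal(q, bruteBH(p), tolerance = 1e-12)
        expect_true(all(q >= p - 1e-12) && all(q <= 1))
        perm <- sample(seq_along(p))
        expect_equal(bhAdjust(p[perm]), q[perm])
    }
})

test_that("aggregateUnique unions without duplicates", {
    got <- aggregateUnique(list(GeneSet("s1", c("A", "B")),
                                GeneSet("s2", c("B", "C"))))
    expect_setequal(geneIds(got), c("A", "B", "C"))
    one <- GeneSet("only", c("X", "Y"))
    expect_setequal(geneIds(aggregateUnique(list(one))), geneIds(one))
})

test_that("gene-set files round-trip in GMT and TSV form", {
    sets <- list(GeneSet("meiosis_a", c("Stra8", "Meiosin", "Rec8")),
                 GeneSet("meiosis_b", c("Rec8", "Sycp3")))
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeGeneSets(sets, gmt)
    back <- readGeneSets(gmt)
    expect_named(back, c("meiosis_a", "meiosis_b"))
    expect_setequal(geneIds(back$meiosis_b), c("Rec8", "Sycp3"))
    expect_setequal(geneIds(aggregateUnique(back)),
                    c("Stra8", "Meiosin", "Rec8", "Sycp3"))

    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("set\tgene", "s1\tStra8", "s1\tRec8", "s2\tSycp3"), tsv)
    back2 <- readGeneSets(tsv)
    expect_setequal(geneIds(back2$s1), c("Stra8", "Rec8"))
})

test_that("phase annotations read, write and validate", {
    ann <- PhaseAnnotation(c("Mcm2", "Pcna", "Ccnb1"),
                           c("G1/S", "S", "M"))
    path <- withr::local_tempfile(fileext = ".tsv")
    writePhaseAnnotation(ann, path)
    back <- readPhaseAnnotation(path)
    expect_identical(phaseOf(back), phaseOf(ann))
    expect_error(PhaseAnnotation("Mcm2", "G0"), "unrecognised")
    expect_error(PhaseAnnotation(c("Mcm2", "Mcm2"), c("G1/S", "S")),
                 "exactly one phase")
})

test_that("TPM matrices load into a SummarizedExperiment", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene\ts1\ts2", "Mcm2\t5.5\t0", "Pcna\t1\t2"), path)
    se <- readTpmMatrix(path, groups = c("WT", "KO"))
    expect_s4_class(se, "SummarizedExperiment")
    expect_equal(dim(se), c(2L, 2L))
    expect_setequal(geneIds(filterExpressed(se, 1, 1L)),
                    c("Mcm2", "Pcna"))
})
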