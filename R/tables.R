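## File I/O, dataset merging/filtering, regulated-set definitions and the
## shared multiple-testing utility.

#' Read a differential-expression table
#'
#' Reads a tab-delimited file with a header into a [DETable-class]. Column
#' names are configurable; a file without a \code{padj} (or \code{pvalue})
#' column is accepted with a warning and those values set missing. If an
#' \code{expressed} column is present it is used, otherwise every row is
#' marked expressed.
#'
#' @param path path to a tab-delimited UTF-8 file with header.
#' @param contrastId contrast label stored in the result.
#' @param columns named character vector mapping the canonical names
#'   \code{gene}, \code{log2fc}, \code{pvalue}, \code{padj} (and optionally
#'   \code{expressed}) to the column names in the file.
#' @return A [DETable-class].
#' @seealso [writeDETable()]
#' @export
readDETable <- function(path, contrastId,
                        columns = c(gene = "gene", log2fc = "log2fc",
                                    pvalue = "pvalue", padj = "padj")) {
    raw <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8")
    need <- c("gene", "log2fc")
    for (nm in need)
        if (!columns[[nm]] %in% colnames(raw))
            stop("column ", sQuote(columns[[nm]]), " (", nm,
                 ") not found in ", path)
    getNum <- function(nm) {
        col <- columns[[nm]]
        if (is.na(col) || !col %in% colnames(raw)) {
            warning("no ", sQuote(nm), " column in ", basename(path),
                    "; values set to missing", call. = FALSE)
            return(rep(NA_real_, nrow(raw)))
        }
        v <- raw[[col]]
        num <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & v != "" & is.na(num))
        if (length(bad))
            stop("unparseable numeric value ", sQuote(v[bad[1L]]),
                 " in column ", sQuote(col), ", row ", bad[1L])
        num
    }
    gene <- as.character(raw[[columns[["gene"]]]])
    if (anyDuplicated(gene))
        stop("duplicate gene symbol(s): ",
             paste(unique(gene[duplicated(gene)]), collapse = ", "))
    expressed <- if ("expressed" %in% names(columns) &&
                     columns[["expressed"]] %in% colnames(raw))
        as.logical(raw[[columns[["expressed"]]]])
    else if ("expressed" %in% colnames(raw) &&
             !"expressed" %in% names(columns))
        as.logical(raw[["expressed"]])
    else TRUE
    DETable(gene = gene, log2fc = getNum("log2fc"),
            pvalue = getNum("pvalue"), padj = getNum("padj"),
            expressed = expressed, contrastId = contrastId)
}

#' Write a DETable to a tab-delimited file
#'
#' The written file round-trips through [readDETable()] field-for-field.
#'
#' @param x a [DETable-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDETable <- function(x, path) {
    stopifnot(is(x, "DETable"))
    write.table(as.data.frame(x), file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a TPM expression matrix
#'
#' Reads a tab-delimited genes-by-samples matrix (first column gene symbols)
#' into a \linkS4class{SummarizedExperiment} with assay \code{"tpm"}.
#'
#' @param path path to the tab-delimited file.
#' @param groups optional character vector of group labels, one per sample
#'   column, stored in \code{colData(x)$group}.
#' @return A \linkS4class{SummarizedExperiment}.
#' @export
readTpmMatrix <- function(path, groups = NULL) {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    genes <- as.character(raw[[1L]])
    m <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    if (any(m < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
    cd <- if (is.null(groups)) DataFrame(row.names = colnames(m))
          else DataFrame(group = groups, row.names = colnames(m))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(tpm = m), colData = cd)
}

#' Expression filter: minimum TPM in a minimum number of samples
#'
#' Retains genes with TPM at or above \code{minTpm} (inclusive) in at least
#' \code{minSamples} samples — the conventional "TPM >= 1 in at least three
#' of six samples" style filter.
#'
#' @param x a \linkS4class{SummarizedExperiment} with a \code{"tpm"} (or
#'   first) assay, or a numeric genes-by-samples matrix with rownames.
#' @param minTpm positive expression threshold (inclusive).
#' @param minSamples minimum number of samples meeting the threshold.
#' @return A [GeneSet-class] named \code{"expressed"}.
#' @examples
#' m <- rbind(kept = c(1, 1, 1, 0, 0, 0), dropped = c(1.2, 0.5, 3, 0, 0, 0))
#' geneIds(filterExpressed(m, minTpm = 1, minSamples = 3))
#' @export
filterExpressed <- function(x, minTpm = 1, minSamples = 3L) {
    m <- if (is(x, "SummarizedExperiment")) {
        a <- SummarizedExperiment::assays(x)
        if ("tpm" %in% names(a)) a[["tpm"]] else a[[1L]]
    } else as.matrix(x)
    if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
    .assertScalarNumeric(minTpm, "minTpm", lower = 0, strict = TRUE)
    if (minSamples < 1L || minSamples > ncol(m))
        stop("'minSamples' must lie in [1, ", ncol(m), "]")
    keep <- rowSums(m >= minTpm) >= minSamples
    GeneSet("expressed", rownames(m)[keep])
}

#' Merge differential-expression tables by gene symbol
#'
#' Inner join on gene symbol over two or more contrasts, with per-contrast
#' columns suffixed by their contrast label. Merging is as-printed: no
#' ortholog or alias resolution is attempted.
#'
#' @param tables a list of [DETable-class] objects with distinct contrast
#'   labels.
#' @return A [MergedContrasts-class] with one row per shared gene.
#' @examples
#' a <- DETable(c("x", "y"), c(1, -1), 0.01, 0.02, contrastId = "A")
#' b <- DETable(c("y", "z"), c(2, 0.5), 0.01, 0.02, contrastId = "B")
#' mergeByGene(list(a, b))
#' @export
mergeByGene <- function(tables) {
    if (!is.list(tables) || length(tables) < 2L)
        stop("'tables' must be a list of at least two DETable objects")
    if (!all(vapply(tables, is, logical(1L), "DETable")))
        stop("all elements of 'tables' must be DETable objects")
    ids <- vapply(tables, contrastId, character(1L))
    if (anyDuplicated(ids))
        stop("contrast labels must be distinct: ",
             paste(ids, collapse = ", "))
    shared <- Reduce(intersect, lapply(tables, function(t) t$gene))
    if (length(shared) == 0L)
        stop("no genes are shared between the tables")
    cols <- list(gene = shared)
    for (i in seq_along(tables)) {
        t <- tables[[i]]
        idx <- match(shared, t$gene)
        for (f in c("log2fc", "pvalue", "padj", "expressed"))
            cols[[paste0(f, "_", ids[i])]] <- t[[f]][idx]
    }
    new("MergedContrasts", do.call(DataFrame, c(cols, check.names = FALSE)),
        contrastIds = ids)
}

#' Define up- and downregulated gene sets from a contrast
#'
#' Upregulated genes have log2 fold change (wild-type/knockout) above zero
#' with adjusted p below \code{alpha}; downregulated genes the same with
#' negative fold change. Genes with a missing adjusted p are treated as not
#' significant and belong to neither set.
#'
#' @param table a [DETable-class].
#' @param alpha adjusted-p significance threshold in (0, 1).
#' @return A list with [GeneSet-class] elements \code{upregulated} and
#'   \code{downregulated}, plus \code{dependent}, their union (the
#'   restriction set used by the epistasis analysis).
#' @export
defineRegulatedSets <- function(table, alpha = 0.05) {
    stopifnot(is(table, "DETable"))
    .assertScalarNumeric(alpha, "alpha", 0, 1, strict = TRUE)
    sig <- !is.na(table$padj) & table$padj < alpha
    up <- table$gene[sig & table$log2fc > 0]
    down <- table$gene[sig & table$log2fc < 0]
    id <- contrastId(table)
    list(upregulated = GeneSet(paste0(id, "_up"), up),
         downregulated = GeneSet(paste0(id, "_down"), down),
         dependent = GeneSet(paste0(id, "_dependent"), c(up, down)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction, returned in input order. This is
#' the single multiple-testing utility used throughout the package.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}; \code{NA}s
#'   are propagated and excluded from the family size.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.04, 0.03))
#' @export
bhAdjust <- function(pvalues) {
    p <- as.numeric(pvalues)
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Union of gene sets without duplicates
#'
#' @param sets a list of [GeneSet-class] objects (length >= 1), or character
#'   vectors.
#' @param name label for the aggregated set.
#' @return A [GeneSet-class] holding the union.
#' @export
aggregateUnique <- function(sets, name = "aggregated") {
    if (!is.list(sets) || length(sets) < 1L)
        stop("'sets' must be a non-empty list")
    GeneSet(name, unlist(lapply(sets, .asGeneIds), use.names = FALSE))
}

#' Read gene-set collections
#'
#' Supports GMT (one set per line: name, description, member genes,
#' tab-delimited) and two-column TSV (columns \code{set}, \code{gene}, with
#' header).
#'
#' @param path file path.
#' @param format \code{"gmt"} or \code{"tsv"}; the default guesses from the
#'   file extension.
#' @return A named list of [GeneSet-class] objects.
#' @export
readGeneSets <- function(path, format = c("auto", "gmt", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt"
                  else "tsv"
    if (format == "gmt") {
        lines <- readLines(path, encoding = "UTF-8")
        lines <- lines[nzchar(lines)]
        sets <- lapply(lines, function(l) {
            f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
            if (length(f) < 3L)
                stop("malformed GMT line (need name, description, genes): ",
                     substr(l, 1L, 40L))
            GeneSet(f[1L], f[-(1:2)])
        })
    } else {
        df <- read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
        if (!all(c("set", "gene") %in% colnames(df)))
            stop("two-column TSV gene-set files need 'set' and 'gene' columns")
        sets <- lapply(split(df$gene, df$set), function(g)
            GeneSet(name = "", genes = g))
        for (nm in names(sets)) sets[[nm]]@name <- nm
    }
    names(sets) <- vapply(sets, setName, character(1L))
    sets
}

#' Write gene sets as GMT
#'
#' @param sets a list of [GeneSet-class] objects.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneSets <- function(sets, path) {
    lines <- vapply(sets, function(s)
        paste(c(setName(s), "na", geneIds(s)), collapse = "\t"),
        character(1L))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a phase annotation
#'
#' Two-column TSV (\code{gene}, \code{phase}, with header); phase labels
#' must be among [CELL_CYCLE_PHASES].
#'
#' @param path file path.
#' @return A [PhaseAnnotation-class].
#' @export
readPhaseAnnotation <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (!all(c("gene", "phase") %in% colnames(df)))
        stop("phase annotation files need 'gene' and 'phase' columns")
    PhaseAnnotation(df$gene, df$phase)
}

#' Write a phase annotation as two-column TSV
#'
#' @param annotation a [PhaseAnnotation-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePhaseAnnotation <- function(annotation, path) {
    ph <- phaseOf(annotation)
    write.table(data.frame(gene = names(ph), phase = unname(ph)),
                file = path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

## Pull one contrast's column from a merged table.
.mergedCol <- function(merged, field, contrast) {
    col <- paste0(field, "_", contrast)
    if (!col %in% colnames(merged))
        stop("contrast ", sQuote(contrast), " not present in merged table")
    merged[[col]]
}
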