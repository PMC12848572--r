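Package: koCompare
Title: Comparative Analysis of Paired Knockout Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Statistical toolkit for comparing bulk RNA-seq knockout
    contrasts that share a regulatory program. Implements percentile-rank
    scoring of cell-cycle phase gene sets against log2 fold-change
    distributions, one-tailed hypergeometric overlap tests for regulated
    gene sets, a bootstrap null for Spearman correlation built from random
    gene sets, ordinary-least-squares attenuation (epistasis) slopes with
    confidence intervals, and proportion statistics for cell-labeling count
    data including an exact two-sample binomial power calculation. A
    synthetic-data generator produces paired differential-expression
    tables, count matrices, phase annotations and labeling-index counts
    with known ground truth so that every estimator can be exercised and
    checked by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Transcriptomics, DifferentialExpression, GeneSetEnrichment,
    StatisticalMethod, RNASeq
Config/testthat/edition: 3
RoxygenNote: 7.3.3
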