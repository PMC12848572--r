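## ggplot2 display helpers.

#' Dot-whisker plot of phase scores
#'
#' Median percentile rank per phase with interquartile whiskers, against
#' the 0.5 reference line.
#'
#' @param scores output of [phaseScoreTest()].
#' @return A ggplot object.
#' @export
plotPhaseScores <- function(scores) {
    df <- as.data.frame(scores)
    df$phase <- factor(df$phase, levels = rev(CELL_CYCLE_PHASES))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$median_rank,
                                     y = .data$phase)) +
        ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                            colour = "grey50") +
        ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$q1,
                                             xmax = .data$q3),
                                height = 0.2) +
        ggplot2::geom_point(size = 2.5) +
        ggplot2::xlim(0, 1) +
        ggplot2::labs(x = "log2FC percentile rank", y = NULL) +
        ggplot2::theme_classic()
}

#' Scatter of paired fold changes with the attenuation fit
#'
#' Dependent genes' log2 fold changes in the two contrasts, with the
#' ordinary-least-squares attenuation line and the identity for reference.
#'
#' @param merged a [MergedContrasts-class] over two contrasts.
#' @param fit an [EpistasisFit-class] from [fitAttenuation()].
#' @param dependent the gene set the fit was computed on.
#' @return A ggplot object.
#' @export
plotAttenuation <- function(merged, fit, dependent) {
    x <- .mergedCol(merged, "log2fc", fit@predictorContrast)
    y <- .mergedCol(merged, "log2fc", fit@responseContrast)
    keep <- merged$gene %in% .asGeneIds(dependent)
    df <- data.frame(x = x[keep], y = y[keep])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_point(alpha = 0.4, size = 0.8) +
        ggplot2::geom_abline(slope = 1, intercept = 0,
                             linetype = "dotted", colour = "grey50") +
        ggplot2::geom_abline(slope = fit@slope, intercept = fit@intercept,
                             colour = "red") +
        ggplot2::labs(
            x = paste0("log2FC, ", fit@predictorContrast),
            y = paste0("log2FC, ", fit@responseContrast),
            subtitle = sprintf("slope = %.2f (95%% CI %.2f-%.2f)",
                               fit@slope, fit@ci95[1L], fit@ci95[2L])) +
        ggplot2::theme_classic()
}
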