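#' @importFrom ggplot2 ggplot aes geom_step geom_abline geom_col geom_point
#'   geom_smooth labs coord_equal theme_minimal autoplot
NULL

#' Plot an ROC curve
#'
#' @param x A `composite_performance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_roc <- function(x, ...) {
  ggplot(x$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False-positive rate", y = "True-positive rate",
         title = sprintf("ROC (AUC = %.2f)", x$auc)) +
    theme_minimal()
}

#' @export
autoplot.composite_performance <- function(object, ...) plot_roc(object, ...)

#' Plot the per-chromosome co-mutation histogram
#'
#' Bars show co-mutation events per chromosome split into mutations and
#' CNVs; chromosomes hosting a composite gene are highlighted, the
#' visual signature of chromosysmos enrichment.
#'
#' @param x A `same_chrom_stat` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_chromosome_histogram <- function(x, ...) {
  long <- tidyr::pivot_longer(x$histogram, c("mutation", "cnv"),
                              names_to = "event_type", values_to = "n")
  long$chromosome <- factor(long$chromosome, levels = x$histogram$chromosome)
  ggplot(long, aes(x = .data$chromosome, y = .data$n,
                   fill = .data$event_type,
                   alpha = .data$is_composite_chromosome)) +
    geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    labs(x = "Chromosome", y = "Co-mutation events", fill = "Event type") +
    theme_minimal()
}

#' @export
autoplot.same_chrom_stat <- function(object, ...) plot_chromosome_histogram(object, ...)

#' Plot the complementary-relationship scatter
#'
#' Co-gene frequencies in composite samples against the same genes'
#' frequencies in non-composite samples, with the least-squares line.
#'
#' @param x A `complementary_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_complementary <- function(x, ...) {
  pairs <- attr(x, "pairs")
  ggplot(pairs, aes(x = .data$freq_noncomposite, y = .data$freq_composite)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    labs(x = "Co-mutation frequency, non-composite samples",
         y = "Co-mutation frequency, composite samples",
         title = sprintf("r = %.2f, p = %.2g", x$pearson_r, x$p_value)) +
    theme_minimal()
}

#' @export
autoplot.complementary_fit <- function(object, ...) plot_complementary(object, ...)

#' Plot a substitution spectrum
#'
#' @param x A `substitution_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_substitution_spectrum <- function(x, ...) {
  ggplot(x, aes(x = .data$class, y = .data$fraction)) +
    geom_col(fill = "firebrick") +
    labs(x = "Substitution class", y = "Fraction of SNVs") +
    theme_minimal()
}

#' @export
autoplot.substitution_spectrum <- function(object, ...) {
  plot_substitution_spectrum(object, ...)
}

#' Plot the shuffle-robustness sweep
#'
#' AUC against the fraction of shuffled feature columns.
#'
#' @param x A `shuffle_report` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_shuffle_report <- function(x, ...) {
  ggplot(x, aes(x = .data$fraction, y = .data$auc)) +
    geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    labs(x = "Fraction of features shuffled", y = "Held-out AUC") +
    theme_minimal()
}

#' @export
autoplot.shuffle_report <- function(object, ...) plot_shuffle_report(object, ...)
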