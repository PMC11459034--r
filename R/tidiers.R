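#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the held-out scores of a fitted ensemble
#'
#' @param x A `composite_ensemble`.
#' @param ... Unused.
#' @return The held-out score tibble (one row per test sample).
#' @method tidy composite_ensemble
#' @export
tidy.composite_ensemble <- function(x, ...) x$scores

#' One-row performance summary of a fitted ensemble
#'
#' @param x A `composite_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble of confusion counts, metrics and AUC on the
#'   held-out split.
#' @method glance composite_ensemble
#' @export
glance.composite_ensemble <- function(x, ...) {
  perf <- evaluate_predictions(x$scores$truth, x$scores$score, x$scores$predicted)
  dplyr::bind_cols(perf$confusion, perf$metrics, tibble(auc = perf$auc))
}

#' Tidy a performance object into its ROC points
#'
#' @param x A `composite_performance`.
#' @param ... Unused.
#' @return The ROC tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy composite_performance
#' @export
tidy.composite_performance <- function(x, ...) x$roc

#' One-row summary of a performance object
#'
#' @param x A `composite_performance`.
#' @param ... Unused.
#' @return A one-row tibble of confusion counts, metrics and AUC.
#' @method glance composite_performance
#' @export
glance.composite_performance <- function(x, ...) {
  dplyr::bind_cols(x$confusion, x$metrics, tibble(auc = x$auc))
}

#' Tidy the null distribution of a randomization test
#'
#' @param x A `chromosysmos_test`.
#' @param ... Unused.
#' @return A tibble with one row per iteration (`null_fraction`).
#' @method tidy chromosysmos_test
#' @export
tidy.chromosysmos_test <- function(x, ...) {
  tibble(iteration = seq_along(x$null_fractions),
         null_fraction = x$null_fractions)
}

#' One-row summary of a randomization test
#'
#' @param x A `chromosysmos_test`.
#' @param ... Unused.
#' @return A one-row tibble: observed fraction, null mean, empirical p,
#'   iteration count, event count, seed.
#' @method glance chromosysmos_test
#' @export
glance.chromosysmos_test <- function(x, ...) {
  tibble(
    observed_fraction = x$observed_fraction,
    null_mean = mean(x$null_fractions),
    empirical_p = x$empirical_p,
    n_iterations = x$n_iterations,
    n_events = x$n_events,
    seed = x$seed
  )
}

#' Tidy per-composite-gene same-chromosome fractions
#'
#' @param x A `same_chrom_stat`.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @method tidy same_chrom_stat
#' @export
tidy.same_chrom_stat <- function(x, ...) x$per_gene

#' One-row summary of same-chromosome enrichment
#'
#' @param x A `same_chrom_stat`.
#' @param ... Unused.
#' @return A one-row tibble: pooled fraction, mean per-gene fraction,
#'   event count.
#' @method glance same_chrom_stat
#' @export
glance.same_chrom_stat <- function(x, ...) {
  tibble(pooled_fraction = x$pooled_fraction,
         mean_gene_fraction = x$mean_gene_fraction,
         n_events = x$n_events)
}
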