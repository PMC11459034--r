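#' Fit the composite-mutation predictor for one gene, selection nested in training
#'
#' End-to-end per-gene fit with an unbiased held-out evaluation: the
#' stratum (tumor types bearing composites in the gene) is split into a
#' stratified training set (2/3) and test set (1/3) first; the Fisher
#' co-mutation selection (per tumor type, raw P < `p_threshold`) is run
#' on the training samples only; the binary and distance feature blocks
#' are then built for all samples and the two forests are trained on the
#' training rows and scored on the held-out rows. Nesting the selection
#' inside the split keeps the held-out labels out of the feature choice,
#' so a cohort with no true structure scores near chance.
#'
#' @param cohort A [load_cohort()] object.
#' @param calls Composite calls from [call_composites()].
#' @param composite_gene Target gene symbol.
#' @param config A [model_config()].
#' @param p_threshold Selection threshold on the raw Fisher p (0.05).
#' @param background_multiplier Background threshold multiplier (1.04).
#' @return A list of class `composite_gene_fit`: `fit` (the
#'   [train_composite_ensemble()] object), `performance`
#'   ([evaluate_predictions()] on the held-out split), `features`,
#'   `significant` (selected co-genes), `comutations` (the training-set
#'   selection table).
#' @export
fit_composite_gene <- function(cohort, calls, composite_gene,
                               config = model_config(), p_threshold = 0.05,
                               background_multiplier = 1.04) {
  gene_calls <- filter(calls, .data$gene == composite_gene)
  if (nrow(gene_calls) == 0) {
    abort_stat(sprintf("no composite calls for %s", composite_gene),
               class = "compmut_empty_stratum")
  }
  types <- unique(cohort$samples$tumor_type[
    cohort$samples$sample_id %in% gene_calls$sample_id])
  stratum <- cohort$samples$sample_id[cohort$samples$tumor_type %in% types]
  labels <- factor(
    ifelse(stratum %in% gene_calls$sample_id, "composite", "non_composite"),
    levels = c("non_composite", "composite")
  )
  if (nlevels(droplevels(labels)) < 2) {
    abort_stat("stratum labels contain a single class",
               class = "compmut_single_class")
  }
  set.seed(config$seed)
  idx <- as.vector(caret::createDataPartition(labels, p = config$train_fraction,
                                              list = FALSE))
  train_ids <- stratum[idx]

  res <- purrr::map(types, function(tt) {
    tryCatch(
      test_comutations(cohort, calls, composite_gene, tt,
                       p_threshold = p_threshold,
                       background = compute_background_rate(
                         cohort, tt, multiplier = background_multiplier),
                       sample_ids = train_ids),
      compmut_empty_stratum = function(e) NULL
    )
  })
  res <- bind_rows(res)
  sig <- unique(res$co_gene[res$significant])
  if (length(sig) == 0) {
    abort_stat("no significant co-genes in the training split",
               class = "compmut_no_features")
  }
  features <- build_feature_matrices(cohort, calls, composite_gene, sig)
  # feature rows follow the stratum order used for the split
  stopifnot(identical(features$sample_id, stratum))
  fit <- train_composite_ensemble(features, config, train_index = idx)
  perf <- evaluate_predictions(fit$scores$truth, fit$scores$score,
                               fit$scores$predicted)
  structure(list(fit = fit, performance = perf, features = features,
                 significant = sig, comutations = res),
            class = "composite_gene_fit")
}

#' @export
print.composite_gene_fit <- function(x, ...) {
  cat(sprintf("<composite_gene_fit> %s: %d selected co-genes, held-out AUC %.3f\n",
              x$features$composite_gene, length(x$significant),
              x$performance$auc))
  invisible(x)
}
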