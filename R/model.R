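#' Model configuration for the composite-mutation ensemble
#'
#' @param n_trees Number of trees per random forest (default 100).
#' @param train_fraction Fraction of samples in the training split
#'   (default 2/3; the split is stratified by label).
#' @param seed Integer seed controlling the split and both forests.
#' @param weights Ensemble weights, `c(binary = 0.75, distance = 0.25)`;
#'   must sum to 1. The binary co-mutation model carries the larger
#'   weight, the chromosomal-distance model the smaller.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_trees = 100, train_fraction = 2 / 3, seed = 1,
                         weights = c(binary = 0.75, distance = 0.25)) {
  if (abs(sum(weights) - 1) > 1e-12) abort_validation("weights must sum to 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_validation("train_fraction must be in (0, 1)")
  }
  structure(list(n_trees = n_trees, train_fraction = train_fraction,
                 seed = as.integer(seed), weights = weights),
            class = "model_config")
}

#' Combine the two model probabilities into weighted ensemble scores
#'
#' The composite-class score is `w_binary * p_binary + w_distance *
#' p_distance` (defaults 0.75 / 0.25); the non-composite score is its
#' complement. The predicted label is the class with the highest score;
#' an exact tie resolves to the non-composite class.
#'
#' @param p_binary,p_distance Composite-class probabilities from the
#'   binary co-mutation model and the distance model, over the same
#'   samples.
#' @param config A [model_config()].
#' @param sample_id Optional sample identifiers.
#' @return A tibble with `sample_id` (if given), `p_binary`,
#'   `p_distance`, `score` (weighted composite-class score) and
#'   `predicted` (factor).
#' @examples
#' ensemble_predict(0.8, 0.4, model_config())  # score 0.7 -> composite
#' @export
ensemble_predict <- function(p_binary, p_distance, config = model_config(),
                             sample_id = NULL) {
  if (length(p_binary) != length(p_distance)) {
    abort_validation("probability vectors must cover the same samples")
  }
  w <- config$weights
  score <- w[["binary"]] * p_binary + w[["distance"]] * p_distance
  # tie (score exactly 0.5 for both classes) resolves to non-composite
  predicted <- factor(ifelse(score > 0.5, "composite", "non_composite"),
                      levels = c("non_composite", "composite"))
  out <- tibble(p_binary = p_binary, p_distance = p_distance,
                score = score, predicted = predicted)
  if (!is.null(sample_id)) out <- dplyr::bind_cols(tibble(sample_id = sample_id), out)
  out
}

rf_fit <- function(x, y, n_trees, seed) {
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(x), y = y, ntree = n_trees)
}

rf_prob <- function(model, x) {
  unname(stats::predict(model, as.data.frame(x), type = "prob")[, "composite"])
}

#' Train the weighted two-model random-forest ensemble
#'
#' Splits the samples into a stratified training set (2/3) and test set
#' (1/3) with `caret::createDataPartition`, fits one 100-tree random
#' forest on the binary co-mutation block and one on the
#' chromosomal-distance block (all other hyperparameters at the
#' implementation defaults), and combines the held-out composite-class
#' probabilities with [ensemble_predict()]. Fully reproducible from the
#' config seed.
#'
#' @param features A [build_feature_matrices()] result.
#' @param config A [model_config()].
#' @param train_index Optional integer vector fixing the training rows
#'   (e.g. a split made before feature selection); when `NULL`, a
#'   stratified split is drawn from the config seed.
#' @return A list of class `composite_ensemble`: the two fitted forests,
#'   the config, the train index, and `scores` — a tibble of held-out
#'   `sample_id`, `truth`, `p_binary`, `p_distance`, `score`, `predicted`.
#' @export
train_composite_ensemble <- function(features, config = model_config(),
                                     train_index = NULL) {
  y <- features$labels
  if (nlevels(droplevels(y)) < 2) {
    abort_stat("labels contain a single class; cannot train",
               class = "compmut_single_class")
  }
  if (is.null(train_index)) {
    set.seed(config$seed)
    train_index <- as.vector(caret::createDataPartition(
      y, p = config$train_fraction, list = FALSE))
  }
  idx <- train_index
  xb <- features$binary
  xd <- features$distance
  mb <- rf_fit(xb[idx, , drop = FALSE], y[idx], config$n_trees, config$seed + 1L)
  md <- rf_fit(xd[idx, , drop = FALSE], y[idx], config$n_trees, config$seed + 2L)
  test <- setdiff(seq_along(y), idx)
  pb <- rf_prob(mb, xb[test, , drop = FALSE])
  pd <- rf_prob(md, xd[test, , drop = FALSE])
  scores <- ensemble_predict(pb, pd, config,
                             sample_id = features$sample_id[test])
  scores <- dplyr::bind_cols(scores[, "sample_id"],
                             tibble(truth = y[test]),
                             scores[, c("p_binary", "p_distance", "score", "predicted")])
  structure(list(
    model_binary = mb, model_distance = md, config = config,
    train_index = idx, scores = scores, composite_gene = features$composite_gene
  ), class = "composite_ensemble")
}

#' @export
print.composite_ensemble <- function(x, ...) {
  cat(sprintf("<composite_ensemble> %s: %d held-out samples (%d composite)\n",
              x$composite_gene %||% "?", nrow(x$scores),
              sum(x$scores$truth == "composite")))
  invisible(x)
}

#' Evaluate predictions: confusion matrix, metrics, ROC and AUC
#'
#' Computes the confusion matrix from the predicted labels, the scalar
#' metrics from their closed forms — accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' balanced accuracy `(TP/(TP+FN) + TN/(TN+FP))/2`, precision
#' `TP/(TP+FP)`, TPR (= recall = sensitivity) `TP/(TP+FN)`, FPR
#' `FP/(TN+FP)`, specificity `TN/(TN+FP)` — and the ROC curve by
#' sweeping the ensemble score threshold, with AUC by trapezoidal
#' integration (equal to the Mann-Whitney concordance probability).
#'
#' @param truth Factor of true labels with positive class `composite`.
#' @param score Numeric composite-class scores.
#' @param predicted Factor of predicted labels.
#' @return A list of class `composite_performance`: `confusion` (one-row
#'   tibble TP/FP/TN/FN), `metrics` (one-row tibble), `roc` (tibble of
#'   threshold, fpr, tpr), `auc`.
#' @export
evaluate_predictions <- function(truth, score, predicted) {
  stopifnot(length(truth) == length(score), length(truth) == length(predicted))
  pos <- truth == "composite"
  if (all(pos) || !any(pos)) {
    abort_stat("ROC undefined: test labels contain a single class",
               class = "compmut_single_class")
  }
  pred_pos <- predicted == "composite"
  tp <- sum(pos & pred_pos); fp <- sum(!pos & pred_pos)
  tn <- sum(!pos & !pred_pos); fn <- sum(pos & !pred_pos)
  confusion <- tibble(TP = tp, FP = fp, TN = tn, FN = fn)
  metrics <- tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    tpr = tp / (tp + fn),
    fpr = fp / (tn + fp),
    specificity = tn / (tn + fp)
  )
  roc <- roc_points(truth, score)
  structure(list(confusion = confusion, metrics = metrics, roc = roc,
                 auc = auc_trapezoid(roc)), class = "composite_performance")
}

#' ROC points from scores
#'
#' Step curve from (0, 0) to (1, 1) obtained by sweeping the score
#' threshold over all distinct score values (ties grouped).
#'
#' @inheritParams evaluate_predictions
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(truth, score) {
  pos <- truth == "composite"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # group tied scores
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cumsum(!p)[last] / n_neg),
    tpr = c(0, cumsum(p)[last] / n_pos)
  )
}

#' Trapezoidal AUC of an ROC curve
#'
#' @param roc A [roc_points()] tibble.
#' @return The area under the curve.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' @export
print.composite_performance <- function(x, ...) {
  cat("<composite_performance>\n")
  print(dplyr::bind_cols(x$confusion, x$metrics))
  cat(sprintf("  AUC = %.3f\n", x$auc))
  invisible(x)
}

#' Feature-shuffling robustness of the ensemble
#'
#' For each shuffle fraction f in 10 steps (10% to 100%), a uniformly
#' chosen f-fraction of the co-gene feature columns is permuted across
#' samples — independently per column, and in both the binary and the
#' distance block — after which both forests are retrained and the
#' ensemble re-evaluated on the held-out split. Degrading performance as
#' f grows indicates the model relies on true feature-label structure.
#'
#' @param features A [build_feature_matrices()] result.
#' @param config A [model_config()]; its seed drives column choice,
#'   permutations, split and forests.
#' @param fractions Shuffle fractions (default `seq(0.1, 1, by = 0.1)`).
#' @return A tibble of class `shuffle_report` with one row per fraction:
#'   `fraction`, the scalar metrics and `auc`.
#' @export
shuffle_robustness <- function(features, config = model_config(),
                               fractions = seq(0.1, 1, by = 0.1)) {
  n_feat <- length(features$co_genes)
  n_samp <- length(features$sample_id)
  rows <- purrr::map(seq_along(fractions), function(i) {
    f <- fractions[i]
    shuffled <- features
    set.seed(config$seed + 1000L + i)
    n_shuf <- ceiling(f * n_feat)
    cols <- sample(n_feat, n_shuf)
    for (j in cols) {
      perm <- sample(n_samp)
      shuffled$binary[[j]] <- shuffled$binary[[j]][perm]
      perm <- sample(n_samp)
      shuffled$distance[[j]] <- shuffled$distance[[j]][perm]
    }
    fit <- train_composite_ensemble(shuffled, config)
    perf <- evaluate_predictions(fit$scores$truth, fit$scores$score,
                                 fit$scores$predicted)
    dplyr::bind_cols(tibble(fraction = f), perf$metrics, tibble(auc = perf$auc))
  })
  out <- bind_rows(rows)
  class(out) <- c("shuffle_report", class(out))
  out
}
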