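sep_features <- function(seed = 1, n = 240, p_flip = 0) {
  # planted near-perfect association between one feature and the label
  set.seed(seed)
  labels <- factor(rep(c("composite", "non_composite"), each = n / 2),
                   levels = c("non_composite", "composite"))
  key <- as.integer(labels == "composite")
  flip <- stats::runif(n) < p_flip
  key[flip] <- 1L - key[flip]
  bin <- tibble::tibble(
    K1 = key,
    N1 = stats::rbinom(n, 1, 0.3),
    N2 = stats::rbinom(n, 1, 0.3)
  )
  dist <- tibble::tibble(
    K1 = ifelse(bin$K1 == 1L, 0.01, 1.0),
    N1 = ifelse(bin$N1 == 1L, 0.4, 1.0),
    N2 = ifelse(bin$N2 == 1L, 0.6, 1.0)
  )
  structure(list(sample_id = sprintf("m%03d", seq_len(n)), binary = bin,
                 distance = dist, labels = labels, composite_gene = "X",
                 co_genes = c("K1", "N1", "N2"),
                 distances = NULL), class = "feature_set")
}

test_that("ensemble weighting follows the 0.75/0.25 rule with ties to non-composite", {
  cfg <- model_config()
  out <- ensemble_predict(0.8, 0.4, cfg)
  expect_equal(out$score, 0.75 * 0.8 + 0.25 * 0.4)
  expect_equal(as.character(out$predicted), "composite")

  # 0.75*0.6 + 0.25*0.2 = 0.5: both class scores equal -> non-composite
  tie <- ensemble_predict(0.6, 0.2, cfg)
  expect_equal(tie$score, 0.5)
  expect_equal(as.character(tie$predicted), "non_composite")

  expect_error(ensemble_predict(c(0.5, 0.6), 0.5, cfg),
               class = "compmut_validation_error")
  expect_error(model_config(weights = c(binary = 0.8, distance = 0.3)),
               class = "compmut_validation_error")
})

test_that("degenerate weights reduce the ensemble to a single base model", {
  fs <- sep_features(seed = 2, p_flip = 0.25)
  fit <- train_composite_ensemble(fs, model_config(seed = 7))
  w_bin <- model_config(seed = 7, weights = c(binary = 1, distance = 0))
  only_bin <- ensemble_predict(fit$scores$p_binary, fit$scores$p_distance, w_bin)
  expect_equal(only_bin$score, fit$scores$p_binary)
  w_dist <- model_config(seed = 7, weights = c(binary = 0, distance = 1))
  only_dist <- ensemble_predict(fit$scores$p_binary, fit$scores$p_distance, w_dist)
  expect_equal(only_dist$score, fit$scores$p_distance)
})

test_that("metric formulas match their closed forms on an exhaustive sweep", {
  set.seed(123)
  for (total in 2:20) {
    parts <- expand.grid(tp = 0:total, fp = 0:total, tn = 0:total)
    parts$fn <- total - parts$tp - parts$fp - parts$tn
    parts <- parts[parts$fn >= 0 &
                     (parts$tp + parts$fn) > 0 & (parts$tn + parts$fp) > 0, ]
    parts <- parts[sample(nrow(parts), min(nrow(parts), 40)), ]
    for (i in seq_len(nrow(parts))) {
      tp <- parts$tp[i]; fp <- parts$fp[i]; tn <- parts$tn[i]; fn <- parts$fn[i]
      truth <- factor(rep(c("composite", "non_composite"), c(tp + fn, tn + fp)),
                      levels = c("non_composite", "composite"))
      predicted <- factor(c(rep("composite", tp), rep("non_composite", fn),
                            rep("non_composite", tn), rep("composite", fp)),
                          levels = c("non_composite", "composite"))
      score <- as.numeric(predicted == "composite")
      if (stats::sd(score) == 0) score <- score + seq_along(score) * 1e-9
      perf <- evaluate_predictions(truth, score, predicted)
      expect_equal(unlist(perf$confusion), c(TP = tp, FP = fp, TN = tn, FN = fn))
      expect_equal(perf$metrics$accuracy, (tp + tn) / total)
      expect_equal(perf$metrics$balanced_accuracy,
                   (tp / (tp + fn) + tn / (tn + fp)) / 2)
      if (tp + fp > 0) expect_equal(perf$metrics$precision, tp / (tp + fp))
      expect_equal(perf$metrics$tpr, tp / (tp + fn))
      expect_equal(perf$metrics$fpr, fp / (tn + fp))
      expect_equal(perf$metrics$specificity, tn / (tn + fp))
    }
  }
})

test_that("the worked confusion-matrix example evaluates exactly", {
  truth <- factor(rep(c("composite", "non_composite"), c(4, 6)),
                  levels = c("non_composite", "composite"))
  predicted <- factor(c(rep("composite", 3), "non_composite",
                        rep("non_composite", 5), "composite"),
                      levels = c("non_composite", "composite"))
  perf <- evaluate_predictions(truth, seq(1, 0.1, length.out = 10), predicted)
  expect_equal(unlist(perf$confusion), c(TP = 3L, FP = 1L, TN = 5L, FN = 1L))
  expect_equal(perf$metrics$accuracy, 0.8)
  expect_equal(perf$metrics$balanced_accuracy, (3 / 4 + 5 / 6) / 2)
  expect_equal(perf$metrics$precision, 0.75)
  expect_equal(perf$metrics$tpr, 0.75)
  expect_equal(perf$metrics$fpr, 1 / 6)
})

test_that("AUC equals brute-force concordant-pair counting, with invariances", {
  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    truth <- factor(sample(c("composite", "non_composite"), n, replace = TRUE),
                    levels = c("non_composite", "composite"))
    if (length(unique(truth)) < 2) next
    score <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # induce ties
    roc <- roc_points(truth, score)
    expect_equal(auc_trapezoid(roc), auc_oracle(truth, score), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auc_trapezoid(roc_points(truth, exp(3 * score))),
                 auc_trapezoid(roc), tolerance = 1e-12)
    # label inversion complements the AUC
    flipped <- factor(ifelse(truth == "composite", "non_composite", "composite"),
                      levels = c("non_composite", "composite"))
    expect_equal(auc_trapezoid(roc_points(flipped, score)),
                 1 - auc_trapezoid(roc), tolerance = 1e-12)
    # ROC endpoints
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(9)
  truth <- factor(sample(c("composite", "non_composite"), 60, replace = TRUE),
                  levels = c("non_composite", "composite"))
  score <- stats::runif(60) + 0.5 * (truth == "composite")
  mine <- auc_trapezoid(roc_points(truth, score))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, levels =
    c("non_composite", "composite"), direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("training is deterministic and learns separable structure", {
  fs <- sep_features(seed = 3)
  fit1 <- train_composite_ensemble(fs, model_config(seed = 11))
  fit2 <- train_composite_ensemble(fs, model_config(seed = 11))
  expect_identical(fit1$scores, fit2$scores)
  perf <- evaluate_predictions(fit1$scores$truth, fit1$scores$score,
                               fit1$scores$predicted)
  expect_gt(perf$auc, 0.95)
})

test_that("label-permuted training data scores near chance", {
  fs <- sep_features(seed = 4)
  set.seed(13)
  aucs <- replicate(5, {
    fs_null <- fs
    fs_null$labels <- sample(fs$labels)
    fit <- train_composite_ensemble(fs_null, model_config(seed = 17))
    evaluate_predictions(fit$scores$truth, fit$scores$score,
                         fit$scores$predicted)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("single-class inputs raise typed errors", {
  fs <- sep_features(seed = 5)
  fs$labels <- factor(rep("non_composite", length(fs$labels)),
                      levels = c("non_composite", "composite"))
  expect_error(train_composite_ensemble(fs, model_config(seed = 1)),
               class = "compmut_single_class")
  truth <- factor(rep("composite", 4), levels = c("non_composite", "composite"))
  expect_error(evaluate_predictions(truth, runif(4), truth),
               class = "compmut_single_class")
})

test_that("a shuffle sweep produces one row per fraction with sane metrics", {
  fs <- sep_features(seed = 6, n = 120)
  rep <- shuffle_robustness(fs, model_config(seed = 19),
                            fractions = c(0.2, 0.6, 1.0))
  expect_equal(rep$fraction, c(0.2, 0.6, 1.0))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
})
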