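# Stratified cross-validation, the metric suite and the significance tests.

#' Stratified k-fold splits
#'
#' Partitions indices into `k` disjoint evaluation folds that preserve
#' class proportions: within each class, indices are shuffled and dealt
#' round-robin, so per-class evaluation counts differ by at most one
#' across folds. Deterministic given `seed`.
#'
#' @param labels Class label vector (any type with at least `k` members
#'   per class).
#' @param k Number of folds.
#' @param seed Integer seed.
#'
#' @return List of `k` elements, each `list(train =, eval =)` index
#'   vectors.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2)
  classes <- unique(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("infeasible: class ", names(tab)[which.min(tab)], " has ",
         min(tab), " members, fewer than k = ", k, call. = FALSE)
  }
  fold_of <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    list(train = which(fold_of != i), eval = which(fold_of == i))
  })
}

#' Classification metrics for one evaluation set
#'
#' Computes accuracy, macro F1 (unweighted mean of per-class F1), macro
#' sensitivity (unweighted mean of per-class recall), macro one-vs-rest
#' AUC (for two classes equal to the rank-sum AUC, ties counted one half)
#' and the confusion matrix with rows = true class, columns = predicted.
#'
#' @param true_labels,predicted_labels Integer 0/1 vectors of equal
#'   length.
#' @param scores Class-1 probabilities (or any monotone score).
#'
#' @return A `fold_metrics` list: `accuracy`, `f1_macro`,
#'   `sensitivity_macro`, `auc_macro`, `confusion` (2x2 integer matrix),
#'   `n`.
#' @export
compute_metrics <- function(true_labels, predicted_labels, scores) {
  n <- length(true_labels)
  stopifnot(length(predicted_labels) == n, length(scores) == n, n > 0)
  if (length(unique(true_labels)) < 2) {
    stop("AUC undefined: a single distinct true class", call. = FALSE)
  }
  tf <- factor(true_labels, levels = c(0, 1))
  pf <- factor(predicted_labels, levels = c(0, 1))
  confusion <- unclass(table(true = tf, predicted = pf))
  storage.mode(confusion) <- "integer"

  accuracy <- sum(diag(confusion)) / n
  recall <- diag(confusion) / rowSums(confusion)
  f1 <- vapply(1:2, function(i) {
    tp <- confusion[i, i]
    denom <- 2 * tp + sum(confusion[-i, i]) + sum(confusion[i, -i])
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))

  r <- rank(scores)
  n1 <- sum(true_labels == 1)
  n0 <- n - n1
  auc <- (sum(r[true_labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)

  structure(list(accuracy = accuracy,
                 f1_macro = mean(f1),
                 sensitivity_macro = mean(recall),
                 auc_macro = auc,
                 confusion = confusion,
                 n = n),
            class = "fold_metrics")
}

#' Row-normalize a confusion matrix
#'
#' @param confusion Square count matrix, rows = true class.
#' @return Matrix whose rows each sum to 1.
#' @export
normalize_confusion <- function(confusion) {
  sweep(confusion, 1, rowSums(confusion), "/")
}

#' Chi-squared test of independence on a confusion matrix
#'
#' Pearson chi-squared on the 2x2 true-by-predicted table, one degree of
#' freedom, without continuity correction.
#'
#' @param confusion 2x2 count matrix with all marginal totals positive.
#' @return List with `statistic` and `p_value`.
#' @export
chi_squared_confusion <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(2, 2)))
  if (any(rowSums(confusion) == 0) || any(colSums(confusion) == 0)) {
    stop("chi-squared undefined: a marginal total is zero", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(confusion, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' One-sample proportion z test of accuracy against a baseline
#'
#' `z = (accuracy - p0) / sqrt(p0 * (1 - p0) / n)` with a two-sided normal
#' p value; used to compare overall accuracy against the 50% chance level
#' of a balanced task.
#'
#' @param accuracy Observed proportion in `[0, 1]`.
#' @param n Number of evaluated predictions.
#' @param p0 Null proportion (default 0.5).
#' @return List with `z` and `p_value`.
#' @export
proportion_z_test <- function(accuracy, n, p0 = 0.5) {
  stopifnot(n > 0, accuracy >= 0, accuracy <= 1, p0 > 0, p0 < 1)
  z <- (accuracy - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Cross-validated training and evaluation of the classifier
#'
#' Runs stratified `k`-fold cross-validation: one model per fold (fold
#' models are seeded as `seed + fold`), metrics on each held-out fold,
#' mean and sample standard deviation (k - 1 denominator) across folds,
#' the chi-squared test of independence on the best fold's confusion
#' matrix (best = highest fold accuracy), the one-sample proportion z test
#' on the pooled held-out accuracy (n = dataset size), and a one-sample
#' t test of the k fold accuracies against 0.5.
#'
#' @param dataset A `scenario_dataset` from [build_scenario()] (or any
#'   list with `data` and `labels`).
#' @param config A [model_config()].
#' @param k Number of folds.
#' @param seed Seed governing the splits and the per-fold model seeds.
#'
#' @return A `cv_summary`: `folds` (list of `fold_metrics`), `metrics`
#'   (per-fold data frame), `mean`, `sd`, `best_fold`, `chi_squared`,
#'   `proportion_test`, `t_test`, `pooled` (held-out truth, predictions
#'   and scores in dataset order).
#' @export
cross_validate <- function(dataset, config, k = 5, seed = 1L) {
  data <- dataset$data
  labels <- dataset$labels
  splits <- stratified_kfold(labels, k = k, seed = seed)
  n <- length(labels)
  pooled_pred <- integer(n)
  pooled_score <- numeric(n)
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + i)
    fit <- train_fold(data[splits[[i]]$train, , drop = FALSE],
                      labels[splits[[i]]$train], cfg_i)
    pr <- predict.diurnal_model(fit, data[splits[[i]]$eval, , drop = FALSE])
    ev <- splits[[i]]$eval
    pooled_pred[ev] <- pr$labels
    pooled_score[ev] <- pr$prob1
    folds[[i]] <- compute_metrics(labels[ev], pr$labels, pr$prob1)
  }
  metric_names <- c("accuracy", "f1_macro", "sensitivity_macro", "auc_macro")
  metrics <- as.data.frame(lapply(metric_names, function(m) {
    vapply(folds, function(f) f[[m]], numeric(1))
  }), col.names = metric_names)
  metrics <- cbind(fold = seq_len(k), metrics)
  best <- which.max(metrics$accuracy)
  pooled_acc <- mean(pooled_pred == labels)
  structure(
    list(folds = folds,
         metrics = metrics,
         mean = colMeans(metrics[metric_names]),
         sd = vapply(metrics[metric_names], stats::sd, numeric(1)),
         best_fold = best,
         chi_squared = chi_squared_confusion(folds[[best]]$confusion),
         proportion_test = proportion_z_test(pooled_acc, n),
         t_test = local({
           tt <- stats::t.test(metrics$accuracy, mu = 0.5)
           list(statistic = unname(tt$statistic),
                p_value = unname(tt$p.value))
         }),
         pooled = list(true = labels, predicted = pooled_pred,
                       score = pooled_score, accuracy = pooled_acc),
         k = k, seed = seed),
    class = "cv_summary"
  )
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("cross-validation over", x$k, "folds\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-18s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  cat(sprintf("  chi-squared (best fold) %.2f, p = %.3g\n",
              x$chi_squared$statistic, x$chi_squared$p_value))
  cat(sprintf("  proportion z (pooled)   %.2f, p = %.3g\n",
              x$proportion_test$z, x$proportion_test$p_value))
  invisible(x)
}
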