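## Classification metrics and the ten-fold cross-validation protocol.
## Note on naming: per-class "specificity" here is precision, TP/(TP+FP) —
## the fraction of predictions for a class that are correct — matching the
## field's usage for this task; the conventional true-negative-rate
## specificity is also reported for completeness.

#' Build a confusion matrix
#'
#' @param true_labels,predicted_labels Integer labels in `[0, n)`.
#' @param n Number of classes.
#' @return A `ConfusionMatrix`: n x n integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(true_labels, predicted_labels, n) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  all_lab <- c(true_labels, predicted_labels)
  if (length(all_lab) && (min(all_lab) < 0L || max(all_lab) >= n))
    stop("labels must lie in [0, ", n, ")")
  m <- matrix(0L, n, n, dimnames = list(true = seq_len(n) - 1L,
                                        predicted = seq_len(n) - 1L))
  for (i in seq_along(true_labels))
    m[true_labels[[i]] + 1L, predicted_labels[[i]] + 1L] <-
      m[true_labels[[i]] + 1L, predicted_labels[[i]] + 1L] + 1L
  structure(m, class = c("ConfusionMatrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = trace/total; per-class precision TP/(TP+FP) and recall
#' TP/(TP+FN); macro values are unweighted class means, with classes that
#' were never predicted (or never occur) contributing 0 to the respective
#' macro mean (flagged in the per-class table). The conventional
#' true-negative-rate specificity TN/(TN+FP) is reported alongside.
#'
#' @param cm A [confusion()] matrix.
#' @return List with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_tnr`, and `per_class` (data frame with class, support, TP/FP/FN
#'   counts, precision, recall, tnr, and flags for undefined ratios).
#' @export
metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  n <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  tnr <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  per_class <- data.frame(class = seq_len(n) - 1L,
                          support = rowSums(cm), tp = tp, fp = fp, fn = fn,
                          precision = precision, recall = recall, tnr = tnr,
                          never_predicted = tp + fp == 0,
                          never_true = tp + fn == 0)
  if (any(per_class$never_predicted))
    message("metrics: ", sum(per_class$never_predicted),
            " class(es) never predicted; their precision counts as 0")
  list(accuracy = sum(tp) / total,
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_tnr = mean(tnr),
       per_class = per_class)
}

#' Stratified k-fold cross-validation
#'
#' Partitions items into `n_folds` label-stratified test partitions; trains
#' on the complement of each and evaluates on it. Partitions are verified to
#' be pairwise disjoint and to cover the dataset exactly once.
#'
#' @param x Feature matrix (rows = items).
#' @param y Integer labels in `[0, n_classes)`.
#' @param train_fn `function(x_train, y_train) -> model`.
#' @param predict_fn `function(model, x_test) -> integer labels`.
#' @param n_folds Number of partitions (default 10).
#' @param seed Seed for the partition shuffle.
#' @return A `CVReport`: list with `per_fold` (list of [metrics()] results),
#'   `aggregate` (mean and sd of accuracy, macro precision, macro recall
#'   over partitions), `pooled` ([metrics()] of the pooled confusion
#'   matrix), and `assignment` (partition index per item).
#' @export
ten_fold_cv <- function(x, y, train_fn, predict_fn, n_folds = 10L, seed = 1L) {
  n <- length(y)
  if (n < n_folds) stop("fewer items (", n, ") than partitions (", n_folds, ")")
  if (any(table(y) < n_folds))
    warning("some classes have fewer than ", n_folds,
            " items; stratification degrades")
  set.seed(seed)
  assignment <- integer(n)
  offset <- 0L  # rotate the fold sequence across classes so no partition
                # starves when class counts are below n_folds
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    assignment[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  stopifnot(all(assignment >= 1L), sum(tabulate(assignment, n_folds)) == n)

  n_classes <- max(y) + 1L
  per_fold <- vector("list", n_folds)
  pooled <- matrix(0L, n_classes, n_classes)
  for (k in seq_len(n_folds)) {
    te <- which(assignment == k)
    tr <- which(assignment != k)
    model <- train_fn(x[tr, , drop = FALSE], y[tr])
    pred <- predict_fn(model, x[te, , drop = FALSE])
    cm <- confusion(y[te], pred, n_classes)
    pooled <- pooled + unclass(cm)
    per_fold[[k]] <- metrics(cm)
  }
  acc <- vapply(per_fold, `[[`, numeric(1), "accuracy")
  prec <- vapply(per_fold, `[[`, numeric(1), "macro_precision")
  rec <- vapply(per_fold, `[[`, numeric(1), "macro_recall")
  structure(list(
    per_fold = per_fold,
    aggregate = data.frame(
      metric = c("accuracy", "macro_precision", "macro_recall"),
      mean = c(mean(acc), mean(prec), mean(rec)),
      sd = c(stats::sd(acc), stats::sd(prec), stats::sd(rec))),
    pooled = metrics(structure(pooled, class = c("ConfusionMatrix", "matrix"))),
    assignment = assignment), class = "CVReport")
}
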