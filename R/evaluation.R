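# Confusion-matrix accounting and imbalance-aware metrics: G-Mean (the
# geometric mean of sensitivity and specificity) and the rate-based AUC
# approximation (1 + TPrate - FPrate) / 2. Also the experiment driver:
# train on one set, evaluate on another.

#' Confusion counts of a binary prediction
#'
#' Class 1 (ortholog) is the positive class.
#'
#' @param true_d True 0/1 labels.
#' @param pred Predicted 0/1 labels, same length.
#' @return An object of class `confusion_counts`: `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(true_d, pred) {
  if (length(true_d) != length(pred))
    stop_format("label vectors differ in length (%d vs %d)",
                length(true_d), length(pred))
  confusion_counts(tp = sum(true_d == 1L & pred == 1L),
                   fn = sum(true_d == 1L & pred == 0L),
                   fp = sum(true_d == 0L & pred == 1L),
                   tn = sum(true_d == 0L & pred == 0L))
}

#' Construct confusion counts directly
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_counts")
}

check_both_classes <- function(counts) {
  if (counts$tp + counts$fn == 0)
    stop_format("no positive instances; sensitivity undefined")
  if (counts$fp + counts$tn == 0)
    stop_format("no negative instances; specificity undefined")
}

#' G-Mean: geometric mean of sensitivity and specificity
#'
#' `sqrt(TP/(TP+FN) * TN/(FP+TN))`. A predictor that ignores the minority
#' class scores 0 (no smoothing).
#'
#' @param counts A [confusion_counts()].
#' @return A value in \[0, 1\].
#' @export
gmean <- function(counts) {
  check_both_classes(counts)
  sens <- counts$tp / (counts$tp + counts$fn)
  spec <- counts$tn / (counts$fp + counts$tn)
  sqrt(sens * spec)
}

#' Rate-based AUC approximation
#'
#' `(1 + TPrate - FPrate) / 2`, the area under the single-point ROC of a
#' hard classifier; not a score-ranking ROC integral.
#'
#' @param counts A [confusion_counts()].
#' @return A value in \[0, 1\].
#' @export
auc_from_rates <- function(counts) {
  check_both_classes(counts)
  tpr <- counts$tp / (counts$tp + counts$fn)
  fpr <- counts$fp / (counts$fp + counts$tn)
  (1 + tpr - fpr) / 2
}

#' Full metric set from confusion counts
#'
#' @param counts A [confusion_counts()].
#' @return An object of class `eval_metrics`: `sensitivity`,
#'   `specificity`, `tp_rate`, `fp_rate`, `g_mean`, `auc` and the counts.
#' @export
eval_metrics <- function(counts) {
  check_both_classes(counts)
  sens <- counts$tp / (counts$tp + counts$fn)
  spec <- counts$tn / (counts$fp + counts$tn)
  structure(list(sensitivity = sens, specificity = spec,
                 tp_rate = sens, fp_rate = 1 - spec,
                 g_mean = sqrt(sens * spec),
                 auc = (1 + sens - (1 - spec)) / 2,
                 counts = counts),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d\n",
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$tn))
  cat(sprintf("TPrate %.4f  TNrate %.4f  G-Mean %.4f  AUC %.4f\n",
              x$tp_rate, x$specificity, x$g_mean, x$auc))
  invisible(x)
}

#' Train on one decision system, evaluate on another
#'
#' Applies the configured imbalance treatment to the training set only
#' (ROS resampling and/or cost-sensitive weighting, the latter with
#' C(+|-) = IR of the untreated training set), trains the learner, and
#' scores its predictions on the test set.
#'
#' @param train,test `decision_system`s with the same feature schema.
#' @param algo `"svm"` or `"rf"`.
#' @param ros_percent RS percentage for random oversampling, or `NULL`
#'   for none.
#' @param cost_sensitive Use misclassification-cost instance weights
#'   (random forest only).
#' @param svm An [svm_params()].
#' @param rf An [rf_params()].
#' @param seed Seed for the ROS draw.
#' @return A list of class `pod_experiment`: `metrics`
#'   ([eval_metrics()]), `model`, `train_stats`, `test_stats`,
#'   `predictions`.
#' @export
run_experiment <- function(train, test, algo = c("svm", "rf"),
                           ros_percent = NULL, cost_sensitive = FALSE,
                           svm = svm_params(), rf = rf_params(),
                           seed = 42L) {
  algo <- match.arg(algo)
  stopifnot(inherits(train, "decision_system"),
            inherits(test, "decision_system"))
  if (ncol(train$features) != ncol(test$features))
    stop_format("train and test feature schemas differ")
  train_stats <- class_stats(train)
  test_stats <- class_stats(test)
  weights <- NULL
  if (cost_sensitive) {
    if (algo != "rf")
      stop_format("cost-sensitive weighting is defined for the random forest")
    if (is.na(train_stats$ir)) stop_format("IR undefined: no minority instances")
  }
  fit_set <- train
  if (!is.null(ros_percent))
    fit_set <- random_oversample(train, ros_params(ros_percent, seed))
  if (cost_sensitive)
    weights <- cost_weights(fit_set$d, cost_params(max(1, train_stats$ir)))
  model <- if (algo == "svm") train_svm(fit_set, svm)
           else train_rf(fit_set, rf, weights = weights)
  pred <- predict(model, test)
  metrics <- eval_metrics(confusion(test$d, pred))
  structure(list(metrics = metrics, model = model,
                 train_stats = train_stats, test_stats = test_stats,
                 predictions = pred),
            class = "pod_experiment")
}

#' @export
print.pod_experiment <- function(x, ...) {
  cat(sprintf("<pod_experiment: %s>\n", x$model$kind))
  cat("train "); print(x$train_stats)
  cat("test  "); print(x$test_stats)
  print(x$metrics)
  invisible(x)
}
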