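# Imbalance treatments (random oversampling, cost-sensitive weighting)
# and the two learner families: a linear hinge-loss SVM with L2 penalty
# (full-batch subgradient descent) and a random forest (via ranger).

#' Random-oversampling parameters
#'
#' @param rs_percent Resampling size RS as a percentage: after ROS the
#'   minority count equals `round(rs_percent/100 * majority count)`.
#'   RS = 100 balances the classes; RS = 130 overshoots the majority by
#'   30 percent.
#' @param seed Integer seed for the resampling draw.
#' @return An object of class `ros_params`.
#' @export
ros_params <- function(rs_percent = 100, seed = 42L) {
  stopifnot(rs_percent > 0)
  structure(list(rs_percent = rs_percent, seed = as.integer(seed)),
            class = "ros_params")
}

#' Misclassification-cost parameters
#'
#' The cost of missing an ortholog, C(+|-), is set to the imbalance ratio
#' and the cost of a false positive, C(-|+), to 1, so the two classes
#' carry equal total weight.
#'
#' @param cost_fn_pos Cost of misclassifying a minority (ortholog)
#'   instance; typically the IR.
#' @param cost_fp_neg Cost of misclassifying a majority instance
#'   (default 1).
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(cost_fn_pos, cost_fp_neg = 1) {
  stopifnot(cost_fn_pos >= 1)
  structure(list(cost_fn_pos = cost_fn_pos, cost_fp_neg = cost_fp_neg),
            class = "cost_params")
}

#' Linear SVM parameters
#'
#' @param reg_param L2 regularization strength (lambda); 1.0, 0.5 and 0.0
#'   are the standard presets, 0 meaning unregularized.
#' @param iterations Number of subgradient iterations (default 100).
#' @param step_size Base step size; the step at iteration t is
#'   `step_size / sqrt(t)` (default 1).
#' @param batch_fraction Fraction of the training set used per iteration
#'   (default 1 = full batch, deterministic).
#' @param seed Seed for minibatch sampling when `batch_fraction < 1`.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(reg_param = 0.5, iterations = 100L, step_size = 1,
                       batch_fraction = 1, seed = 42L) {
  stopifnot(reg_param >= 0, iterations >= 1, step_size > 0,
            batch_fraction > 0, batch_fraction <= 1)
  structure(list(reg_param = reg_param, iterations = as.integer(iterations),
                 step_size = step_size, batch_fraction = batch_fraction,
                 seed = as.integer(seed)),
            class = "svm_params")
}

#' Random-forest parameters
#'
#' @param n_trees Number of trees (default 100).
#' @param attrs_per_node Candidate attributes per split (default 3, i.e.
#'   `int(log2(6) + 1)` for the 6-attribute system).
#' @param seed Integer seed for bootstrap and feature subsampling.
#' @return An object of class `rf_params`.
#' @export
rf_params <- function(n_trees = 100L, attrs_per_node = 3L, seed = 42L) {
  stopifnot(n_trees >= 1, attrs_per_node >= 1, attrs_per_node <= 6)
  structure(list(n_trees = as.integer(n_trees),
                 attrs_per_node = as.integer(attrs_per_node),
                 seed = as.integer(seed)),
            class = "rf_params")
}

#' Random oversampling of the minority class
#'
#' Majority rows are untouched and every original minority row is kept;
#' additional minority rows are drawn with replacement (seeded) until the
#' minority count reaches `round(RS/100 * majority count)`. If that
#' target is below the current minority count no row is removed.
#'
#' @param ds A `decision_system`.
#' @param params A [ros_params()].
#' @return A `decision_system` with replicated minority rows appended.
#' @export
random_oversample <- function(ds, params = ros_params()) {
  stopifnot(inherits(ds, "decision_system"), inherits(params, "ros_params"))
  min_idx <- which(ds$d == 1L)
  maj_n <- sum(ds$d == 0L)
  if (length(min_idx) == 0L) stop_format("minority class is empty")
  target <- as.integer(round_half_up(params$rs_percent / 100 * maj_n))
  extra <- target - length(min_idx)
  if (extra <= 0L) return(ds)
  add <- with_seed(params$seed,
                   sample(min_idx, extra, replace = TRUE))
  subset_pairs(ds, c(seq_len(n_pairs(ds)), add))
}

#' Misclassification-cost instance weights
#'
#' @param d Binary decision vector (1 = ortholog).
#' @param costs A [cost_params()].
#' @return Numeric weight per instance.
#' @export
cost_weights <- function(d, costs) {
  stopifnot(inherits(costs, "cost_params"))
  ifelse(d == 1L, costs$cost_fn_pos, costs$cost_fp_neg)
}

#' Train a linear SVM on a decision system
#'
#' Minimizes the L2-regularized mean hinge loss
#' `lambda/2 ||w||^2 + mean(max(0, 1 - y (w.x + b)))` by subgradient
#' descent with step `step_size / sqrt(t)`; the intercept is not
#' regularized. With `batch_fraction = 1` (default) the fit is
#' deterministic.
#'
#' @param train A `decision_system` containing both classes.
#' @param params An [svm_params()].
#' @return An object of class `pod_model` (kind `"svm"`).
#' @export
train_svm <- function(train, params = svm_params()) {
  stopifnot(inherits(train, "decision_system"), inherits(params, "svm_params"))
  if (length(unique(train$d)) < 2L)
    stop_format("training set contains a single class")
  X <- train$features
  y <- ifelse(train$d == 1L, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- rep(0, p); b <- 0
  lambda <- params$reg_param
  batches <- if (params$batch_fraction < 1) {
    with_seed(params$seed, lapply(seq_len(params$iterations), function(t)
      sample.int(n, max(1L, round(params$batch_fraction * n)))))
  } else NULL
  for (t in seq_len(params$iterations)) {
    idx <- if (is.null(batches)) seq_len(n) else batches[[t]]
    margin <- y[idx] * (X[idx, , drop = FALSE] %*% w + b)
    viol <- margin < 1
    if (any(viol)) {
      gw <- -colSums(X[idx, , drop = FALSE][viol, , drop = FALSE] *
                       y[idx][viol]) / length(idx)
      gb <- -sum(y[idx][viol]) / length(idx)
    } else {
      gw <- rep(0, p); gb <- 0
    }
    eta <- params$step_size / sqrt(t)
    # proximal L2 step: stable for any lambda, including very large values
    w <- (w - eta * gw) / (1 + eta * lambda)
    b <- b - eta * gb
  }
  structure(list(kind = "svm", w = as.numeric(w), b = b, n_features = p,
                 feature_names = colnames(X), params = params),
            class = "pod_model")
}

#' Train a random forest on a decision system
#'
#' A forest of CART-style trees on bootstrap samples with
#' `attrs_per_node` candidate features per split (via ranger). When
#' instance `weights` are supplied (cost-sensitive variant) they enter
#' both the split impurity and the leaf class decision. Prediction is by
#' majority vote.
#'
#' @param train A `decision_system` containing both classes.
#' @param params An [rf_params()].
#' @param weights Optional per-instance weights (e.g. [cost_weights()]).
#' @param bootstrap Draw bootstrap samples per tree (default TRUE); with
#'   FALSE every tree sees the full training set.
#' @return An object of class `pod_model` (kind `"rf"`).
#' @export
train_rf <- function(train, params = rf_params(), weights = NULL,
                     bootstrap = TRUE) {
  stopifnot(inherits(train, "decision_system"), inherits(params, "rf_params"))
  if (length(unique(train$d)) < 2L)
    stop_format("training set contains a single class")
  df <- as.data.frame(train$features)
  df$.d <- factor(train$d, levels = c(0L, 1L))
  fit <- ranger::ranger(
    dependent.variable.name = ".d", data = df,
    num.trees = params$n_trees,
    mtry = min(params$attrs_per_node, ncol(train$features)),
    case.weights = weights,
    replace = bootstrap,
    sample.fraction = 1,
    seed = params$seed, num.threads = 1L,
    classification = TRUE)
  structure(list(kind = "rf", fit = fit,
                 n_features = ncol(train$features),
                 feature_names = colnames(train$features), params = params),
            class = "pod_model")
}

#' @export
print.pod_model <- function(x, ...) {
  cat(sprintf("<pod_model: %s over %d features>\n", x$kind, x$n_features))
  invisible(x)
}

#' Predict ortholog labels for a decision system
#'
#' @param object A `pod_model` from [train_svm()] or [train_rf()].
#' @param ds A `decision_system` with the same feature schema.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per pair; deterministic.
#' @export
predict.pod_model <- function(object, ds, ...) {
  stopifnot(inherits(ds, "decision_system"))
  if (ncol(ds$features) != object$n_features)
    stop_format("feature count mismatch: model has %d, data has %d",
                object$n_features, ncol(ds$features))
  if (n_pairs(ds) == 0L) return(integer(0))
  if (object$kind == "svm") {
    as.integer(ds$features %*% object$w + object$b > 0)
  } else {
    df <- as.data.frame(ds$features)
    colnames(df) <- object$feature_names
    pr <- predict(object$fit, data = df, num.threads = 1L)
    as.integer(as.character(pr$predictions))
  }
}
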