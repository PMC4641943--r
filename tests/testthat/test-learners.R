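test_that("ROS reaches the RS target without touching original rows", {
  ds <- generate_feature_table(8, 2, seed = 51)
  r100 <- random_oversample(ds, ros_params(100, seed = 1))
  expect_equal(sum(r100$d == 1L), 8L)
  expect_equal(n_pairs(r100), 16L)
  r130 <- random_oversample(ds, ros_params(130, seed = 1))
  expect_equal(sum(r130$d == 1L), 10L)  # round(10.4)
  # majority rows unchanged, original minority rows all retained
  expect_identical(r130$features[r130$d == 0L, ], ds$features[ds$d == 0L, ])
  orig_min <- apply(ds$features[ds$d == 1L, ], 1, paste, collapse = ",")
  out_min <- apply(r130$features[r130$d == 1L, ], 1, paste, collapse = ",")
  expect_true(all(orig_min %in% out_min))
  # every replica duplicates an original minority row
  expect_true(all(out_min %in% orig_min))
  # determinism and an RS below the current minority count
  r130b <- random_oversample(ds, ros_params(130, seed = 1))
  expect_identical(r130$features, r130b$features)
  expect_error(random_oversample(generate_feature_table(5, 1, seed = 1) |>
                                   subset_pairs(1:5), ros_params(100)),
               "minority")
})

test_that("cost weights give the classes equal total mass at C(+|-) = IR", {
  d <- c(rep(0L, 8), rep(1L, 2))
  w <- cost_weights(d, cost_params(4))
  expect_equal(unique(w[d == 1L]), 4)
  expect_equal(unique(w[d == 0L]), 1)
  expect_equal(sum(w[d == 1L]), sum(w[d == 0L]))
  expect_equal(unique(cost_weights(d, cost_params(1))), 1)
})

test_that("the linear SVM separates an oversampled separable system", {
  ds <- generate_feature_table(800, 4, separation = 0.6, noise = 0.05,
                               seed = 52)
  bal <- random_oversample(ds, ros_params(100, seed = 1))
  model <- train_svm(bal, svm_params(reg_param = 0.5))
  pred <- predict(model, ds)
  expect_gt(gmean(confusion(ds$d, pred)), 0.95)
  # deterministic full-batch fit
  model2 <- train_svm(bal, svm_params(reg_param = 0.5))
  expect_identical(model$w, model2$w)
  expect_identical(model$b, model2$b)
  # huge regularization collapses the weights to ~0
  big <- train_svm(bal, svm_params(reg_param = 1e6))
  expect_lt(sqrt(sum(big$w^2)), 1e-3)
  # unregularized preset must also converge
  un <- train_svm(bal, svm_params(reg_param = 0))
  expect_gt(gmean(confusion(ds$d, predict(un, ds))), 0.95)
  expect_error(train_svm(subset_pairs(ds, which(ds$d == 0L))), "single class")
})

test_that("the SVM decision agrees with an independent hinge-loss solver", {
  ds <- generate_feature_table(200, 200, separation = 0.5, noise = 0.08,
                               seed = 53)
  ours <- train_svm(ds, svm_params(reg_param = 0.5))
  ref <- e1071::svm(x = ds$features, y = factor(ds$d), kernel = "linear",
                    cost = 1, scale = FALSE)
  ref_pred <- as.integer(as.character(predict(ref, ds$features)))
  our_pred <- predict(ours, ds)
  expect_gt(mean(ref_pred == our_pred), 0.98)
})

test_that("the random forest recovers pure-feature labels and is seeded", {
  ds <- generate_feature_table(300, 20, separation = 0.8, noise = 0.02,
                               seed = 54)
  model <- train_rf(ds, rf_params(n_trees = 50, seed = 3),
                    weights = cost_weights(ds$d, cost_params(15)))
  expect_equal(predict(model, ds), ds$d)
  # all-ones weights are the unweighted variant on the same seed
  w1 <- train_rf(ds, rf_params(n_trees = 25, seed = 3),
                 weights = rep(1, n_pairs(ds)))
  w0 <- train_rf(ds, rf_params(n_trees = 25, seed = 3))
  expect_identical(predict(w1, ds), predict(w0, ds))
  # repeated training with one seed is deterministic
  again <- train_rf(ds, rf_params(n_trees = 25, seed = 3))
  expect_identical(predict(w0, ds), predict(again, ds))
  expect_error(train_rf(subset_pairs(ds, which(ds$d == 1L))), "single class")
})

test_that("one unbagged tree matches an independent CART on axis-split data", {
  set.seed(55)
  n <- 200
  X <- matrix(runif(n * 6), n, 6)
  colnames(X) <- c("S1", "S2", "S3", "S4_w3", "S4_w5", "S4_w7")
  d <- as.integer(X[, "S1"] > 0.5)
  ds <- orthopair:::new_decision_system(
    data.frame(gene_id_1 = sprintf("x%03d", 1:n),
               gene_id_2 = sprintf("y%03d", 1:n)), X, d)
  tree <- train_rf(ds, rf_params(n_trees = 1, attrs_per_node = 6, seed = 1),
                   bootstrap = FALSE)
  ref <- rpart::rpart(factor(d) ~ ., data = as.data.frame(X),
                      method = "class",
                      control = rpart::rpart.control(minsplit = 2, cp = 0))
  Xnew <- matrix(runif(100 * 6), 100, 6)
  colnames(Xnew) <- colnames(X)
  dsnew <- orthopair:::new_decision_system(
    data.frame(gene_id_1 = sprintf("a%03d", 1:100),
               gene_id_2 = sprintf("b%03d", 1:100)), Xnew,
    rep(0L, 100))
  ref_pred <- as.integer(as.character(
    predict(ref, as.data.frame(Xnew), type = "class")))
  expect_equal(predict(tree, dsnew), ref_pred)
})

test_that("prediction is deterministic, shape-checked and empty-safe", {
  ds <- generate_feature_table(40, 10, separation = 0.9, noise = 0.01,
                               seed = 56)
  model <- train_rf(ds, rf_params(n_trees = 100, attrs_per_node = 6,
                                  seed = 2))
  expect_equal(predict(model, ds), ds$d)  # memorizing forest
  expect_identical(predict(model, ds), predict(model, ds))
  expect_equal(predict(model, subset_pairs(ds, integer(0))), integer(0))
  bad <- ds
  bad$features <- ds$features[, 1:4]
  expect_error(predict(model, bad), "mismatch")
})
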