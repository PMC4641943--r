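tiny_system <- function() {
  g1 <- genome("A", c("a1", "a2"), c("MKVWHEAC", "GGSTPNQD"))
  g2 <- genome("B", c("b1", "b2"), c("MKVWHEAD", "WYFILMVA"))
  counts <- rbind(c(3, 0, 3, 0), c(0, 2, 0, 2))
  lcb <- lcb_matrix(counts, 2, 2)
  labels <- label_table("a1", "b1")
  list(g1 = g1, g2 = g2, lcb = lcb, labels = labels,
       params = feature_params(alignment_preset("blosum50")))
}

test_that("the universe is the full cross-product in row-major order", {
  ts <- tiny_system()
  ds <- build_decision_system(ts$g1, ts$g2, ts$lcb, ts$labels, ts$params)
  expect_equal(n_pairs(ds), 4L)
  expect_equal(ds$pairs$gene_id_1, c("a1", "a1", "a2", "a2"))
  expect_equal(ds$pairs$gene_id_2, c("b1", "b2", "b1", "b2"))
  expect_equal(colnames(ds$features),
               c("S1", "S2", "S3", "S4_w3", "S4_w5", "S4_w7"))
  expect_equal(sum(ds$d), 1L)
  expect_equal(ds$d[1], 1L)
  expect_true(all(ds$features >= 0 & ds$features <= 1))
})

test_that("unknown label ids are reported by name", {
  ts <- tiny_system()
  bad <- label_table(c("a1", "nope"), c("b1", "b2"))
  expect_error(
    build_decision_system(ts$g1, ts$g2, ts$lcb, bad, ts$params), "nope")
})

test_that("built features equal per-measure recomputation on a 3x4 fixture", {
  set.seed(41)
  g1 <- random_genome("A", 3, c(10, 20))
  g2 <- random_genome("B", 4, c(10, 20))
  counts <- matrix(rpois(5 * 7, 2), 5, 7)
  lcb <- lcb_matrix(counts, 3, 4)
  params <- feature_params(alignment_preset("blosum622"))
  ds <- build_decision_system(g1, g2, lcb, label_table(), params)
  expect_equal(n_pairs(ds), 12L)

  norm <- compute_normalization(g1, g2, params$alignment)
  lens <- c(g1$length, g2$length)
  et <- params$energy_table
  for (i in 1:3) for (j in 1:4) {
    row <- (i - 1) * 4 + j
    sc <- raw_alignment_scores(g1$seq[[i]], g2$seq[[j]], params$alignment)
    expect_equal(unname(ds$features[row, "S1"]),
                 unname(s1_measure(sc, norm)))
    expect_equal(unname(ds$features[row, "S2"]),
                 unname(s2_length_measure(g1$length[[i]], g2$length[[j]],
                                          min(lens), max(lens))))
    expect_equal(unname(ds$features[row, "S3"]),
                 unname(s3_measure(lcb, i, j)))
    aln <- global_alignment_strings(g1$seq[[i]], g2$seq[[j]],
                                    params$alignment)
    for (w in c(3, 5, 7))
      expect_equal(unname(ds$features[row, paste0("S4_w", w)]),
                   unname(s4_measure(aln$aligned_x, aln$aligned_y, w, et)))
  }
})

test_that("class statistics reproduce printed dataset tables from counts", {
  # S. cerevisiae - K. lactis scale
  cs <- class_stats_from_counts(22646914, 2414)
  expect_equal(orthopair:::round_half_up(cs$ir, 3), 9381.489)
  expect_equal(orthopair:::round_half_up(cs$pct_major, 3), 99.989)
  expect_equal(orthopair:::round_half_up(cs$pct_minor, 3), 0.011)
  # S. cerevisiae - S. pombe scale
  cs2 <- class_stats_from_counts(8090950, 4957)
  expect_equal(orthopair:::round_half_up(cs2$ir, 3), 1632.227)
  expect_equal(orthopair:::round_half_up(cs2$pct_major, 3), 99.939)
  expect_equal(orthopair:::round_half_up(cs2$pct_minor, 3), 0.061)
  # balanced classes and the empty-minority convention
  expect_equal(class_stats_from_counts(10, 10)$ir, 1)
  expect_true(is.na(class_stats_from_counts(10, 0)$ir))
})

test_that("splits are exact-size random partitions, reproducible by seed", {
  expect_equal(split_sizes(22649328, 0.75),
               c(train = 16986996L, test = 5662332L))
  expect_error(split_sizes(100, 1.2), "fraction")

  ds <- generate_feature_table(90, 10, seed = 5)
  sp <- train_test_split(ds, 0.75, seed = 9)
  expect_equal(n_pairs(sp$train), 75L)
  expect_equal(n_pairs(sp$test), 25L)
  key <- function(d) paste(d$pairs$gene_id_1, d$pairs$gene_id_2)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(ds))

  sp2 <- train_test_split(ds, 0.75, seed = 9)
  expect_identical(sp$train$pairs, sp2$train$pairs)
  sp3 <- train_test_split(ds, 0.75, seed = 10)
  expect_false(identical(sp$train$pairs, sp3$train$pairs))
})

test_that("a model transfers unchanged to another system with the schema", {
  train <- generate_feature_table(300, 30, separation = 0.7, noise = 0.05,
                                  seed = 6)
  other <- generate_feature_table(200, 20, separation = 0.7, noise = 0.05,
                                  seed = 7)
  model <- train_svm(random_oversample(train), svm_params(0.5))
  pred <- predict(model, other)
  expect_length(pred, n_pairs(other))
  expect_gt(gmean(confusion(other$d, pred)), 0.9)
})
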