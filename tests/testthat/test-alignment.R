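test_that("kernel scores match the plain-R affine-gap oracle on short pairs", {
  set.seed(11)
  mat <- blosum62()
  params_of <- function(go, ge) alignment_params("BLOSUM62", go, ge)
  for (rep in 1:30) {
    x <- random_protein(sample(2:8, 1))
    y <- random_protein(sample(2:8, 1))
    ge <- sample(1:8, 1); go <- ge + sample(0:7, 1)
    sc <- raw_alignment_scores(x, y, params_of(go, ge))
    expect_equal(sc$local_score,
                 gotoh_oracle(x, y, mat, go, ge, "local"))
    expect_equal(sc$global_score,
                 gotoh_oracle(x, y, mat, go, ge, "global"))
  }
})

test_that("kernel agrees with Biostrings pairwiseAlignment on longer pairs", {
  set.seed(12)
  p <- alignment_preset("blosum50")
  for (rep in 1:8) {
    x <- random_protein(sample(15:40, 1),
                        alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    y <- random_protein(sample(15:40, 1),
                        alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    sc <- raw_alignment_scores(x, y, p)
    bl <- Biostrings::pairwiseAlignment(
      x, y, substitutionMatrix = blosum50(), gapOpening = p$gap_open,
      gapExtension = p$gap_extend, type = "local", scoreOnly = TRUE)
    bg <- Biostrings::pairwiseAlignment(
      x, y, substitutionMatrix = blosum50(), gapOpening = p$gap_open,
      gapExtension = p$gap_extend, type = "global", scoreOnly = TRUE)
    expect_equal(sc$local_score, max(bl, 0))
    expect_equal(sc$global_score, bg)
  }
})

test_that("classic BLOSUM50 15/8 pair scores are reproduced", {
  # frozen from the plain-R oracle: local 23, global -18
  sc <- raw_alignment_scores("HEAGAWGHEE", "PAWHEAE",
                             alignment_preset("blosum50"))
  expect_equal(sc$local_score, 23)
  expect_equal(sc$global_score, -18)
})

test_that("self pairs align along the diagonal and scores are symmetric", {
  p <- alignment_preset("blosum50")
  x <- "MKVWHE"
  diag_sum <- sum(vapply(strsplit(x, "")[[1]],
                         function(a) blosum50()[a, a], 0))
  sc <- raw_alignment_scores(x, x, p)
  expect_equal(sc$local_score, diag_sum)
  expect_equal(sc$global_score, diag_sum)

  y <- "MKWHAE"
  ab <- raw_alignment_scores(x, y, p)
  ba <- raw_alignment_scores(y, x, p)
  expect_equal(ab$local_score, ba$local_score)
  expect_equal(ab$global_score, ba$global_score)
})

test_that("normalization maxima equal an exhaustive loop over all pairs", {
  set.seed(13)
  g1 <- random_genome("A", 3)
  g2 <- random_genome("B", 3)
  p <- alignment_preset("blosum621")
  norm <- compute_normalization(g1, g2, p)
  loc <- glo <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    sc <- raw_alignment_scores(g1$seq[[i]], g2$seq[[j]], p)
    loc[i, j] <- sc$local_score
    glo[i, j] <- sc$global_score
  }
  expect_equal(norm$max_local, max(loc))
  expect_equal(norm$max_global, max(glo))
  expect_true(all(norm$max_local >= loc))
  expect_true(all(norm$max_global >= glo))

  one1 <- genome("a", "a1", g1$seq[[1]])
  one2 <- genome("b", "b1", g2$seq[[1]])
  n1 <- compute_normalization(one1, one2, p)
  sc <- raw_alignment_scores(g1$seq[[1]], g2$seq[[1]], p)
  expect_equal(n1$max_local, sc$local_score)
  expect_equal(n1$max_global, sc$global_score)
})

test_that("a corpus with no positive local score is rejected for S1", {
  g1 <- genome("A", "a1", "WWW")
  g2 <- genome("B", "b1", "DDD")
  expect_error(compute_normalization(g1, g2, alignment_preset("blosum621")),
               "degenerate")
})

test_that("S1 averages the clipped normalized components", {
  norm <- structure(list(max_local = 10, max_global = 8),
                    class = "normalization_constants")
  # the argmax pair of both maxima scores exactly 1
  expect_equal(s1_measure(list(local_score = 10, global_score = 8), norm), 1)
  # clipped negative global: (0.5 + 0) / 2
  expect_equal(s1_measure(list(local_score = 5, global_score = -3), norm),
               0.25)
  # non-positive global maximum zeroes the global component for all pairs
  neg <- structure(list(max_local = 10, max_global = -2),
                   class = "normalization_constants")
  expect_equal(s1_measure(list(local_score = 5, global_score = -1), neg),
               0.25)
  # raising the local score never decreases S1
  s1s <- vapply(seq(0, 10, by = 1), function(l)
    s1_measure(list(local_score = l, global_score = 2), norm), 0)
  expect_true(all(diff(s1s) >= 0))
  # random pairs agree with the direct formula
  set.seed(14)
  for (rep in 1:20) {
    l <- runif(1, -5, 10); g <- runif(1, -8, 8)
    expected <- (max(l / 10, 0) + max(g / 8, 0)) / 2
    expect_equal(s1_measure(list(local_score = l, global_score = g), norm),
                 expected)
  }
})

test_that("S2 is the normalized length difference with its conventions", {
  expect_equal(s2_length_measure(300, 300, 100, 500), 1)
  expect_equal(s2_length_measure(50, 250, 50, 250), 0)
  expect_equal(s2_length_measure(100, 150, 50, 250), 0.75)
  expect_equal(s2_length_measure(150, 100, 50, 250), 0.75)  # symmetric
  expect_equal(s2_length_measure(200, 200, 200, 200), 1)    # degenerate corpus
  expect_error(s2_length_measure(10, 150, 50, 250), "outside")
})

test_that("gap penalties are affine with the first gap residue at go + ge", {
  mat <- blosum62()
  # x = "AA" vs y = "AGA": one single-residue gap in the global alignment
  p <- alignment_params("BLOSUM62", 5, 2)
  sc <- raw_alignment_scores("AA", "AGA", p)
  expect_equal(sc$global_score, 2 * mat["A", "A"] - (5 + 2))
})
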