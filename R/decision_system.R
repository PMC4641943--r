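# The POD decision system: the universe of all cross-genome gene pairs,
# their six feature attributes (S1, S2, S3, S4 at three windows) and the
# curated binary decision d (1 = ortholog). Also class statistics under
# extreme imbalance and reproducible train/test splitting.

#' Feature-computation parameters
#'
#' @param alignment An [alignment_params()] (or preset).
#' @param windows Moving-average window sizes for S4 (default 3, 5, 7).
#' @param energy_table Per-residue energy table for S4.
#' @param alpha Significance level for the S4 correlation test.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(alignment = alignment_preset("blosum50"),
                           windows = c(3L, 5L, 7L),
                           energy_table = default_energy_table(),
                           alpha = 0.05) {
  stopifnot(inherits(alignment, "alignment_params"), length(windows) >= 1,
            all(windows >= 1))
  structure(list(alignment = alignment, windows = as.integer(windows),
                 energy_table = energy_table, alpha = alpha),
            class = "feature_params")
}

# Low-level constructor; validates shapes and the [0, 1] feature range.
new_decision_system <- function(pairs, features, d) {
  stopifnot(is.data.frame(pairs), nrow(pairs) == nrow(features),
            length(d) == nrow(features))
  if (nrow(features) > 0 &&
      (anyNA(features) || any(features < 0) || any(features > 1)))
    stop_format("feature values must lie in [0, 1] with no missing entries")
  if (!all(d %in% c(0L, 1L))) stop_format("decision d must be binary 0/1")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, features = features, d = as.integer(d)),
            class = "decision_system")
}

#' @export
print.decision_system <- function(x, ...) {
  cat(sprintf("<decision_system: %d pairs x %d features; %d orthologs>\n",
              nrow(x$features), ncol(x$features), sum(x$d)))
  invisible(x)
}

#' Number of pairs in a decision system
#' @param ds A `decision_system`.
#' @return Integer row count.
#' @export
n_pairs <- function(ds) nrow(ds$features)

#' Subset a decision system by row index
#'
#' @param ds A `decision_system`.
#' @param idx Integer row indices (duplicates allowed, e.g. oversampling).
#' @return A `decision_system` with the selected rows.
#' @export
subset_pairs <- function(ds, idx) {
  new_decision_system(ds$pairs[idx, , drop = FALSE],
                      ds$features[idx, , drop = FALSE], ds$d[idx])
}

#' Build the POD decision system for a genome pair
#'
#' Enumerates every pair (x_i, y_j), i over genome 1, j over genome 2, in
#' row-major order (genome 1 outer), computes the six features with shared
#' normalization constants, and labels each pair by the curated ortholog
#' table.
#'
#' @param genome1,genome2 [genome()]s with n and m genes.
#' @param lcb An [lcb_matrix()] whose columns match the two genomes.
#' @param labels A [label_table()] of curated ortholog pairs; every id
#'   must resolve against the genomes.
#' @param params A [feature_params()].
#' @return A `decision_system` with n*m rows and feature columns
#'   `S1, S2, S3, S4_w<W>...`.
#' @export
build_decision_system <- function(genome1, genome2, lcb, labels, params) {
  stopifnot(inherits(genome1, "genome"), inherits(genome2, "genome"),
            inherits(lcb, "lcb_matrix"), inherits(params, "feature_params"))
  n <- length(genome1$gene_id); m <- length(genome2$gene_id)
  if (lcb$n != n || lcb$m != m)
    stop_format("LCB matrix shape (%d + %d) does not match genomes (%d + %d)",
                lcb$n, lcb$m, n, m)
  unknown <- c(setdiff(labels$gene_id_1, genome1$gene_id),
               setdiff(labels$gene_id_2, genome2$gene_id))
  if (length(unknown))
    stop_format("label id(s) not found in genomes: %s",
                paste(unique(unknown), collapse = ", "))

  ap <- params$alignment
  scores <- cross_alignment_scores(genome1, genome2, ap)
  norm <- compute_normalization(scores = scores, params = ap)
  s1 <- s1_measure(list(local_score = scores$local,
                        global_score = scores$global), norm)
  s1 <- matrix(s1, n, m)

  lens <- c(genome1$length, genome2$length)
  s2 <- outer(genome1$length, genome2$length,
              function(a, b) s2_length_measure(a, b, min(lens), max(lens)))

  s3 <- s3_all(lcb)

  w <- params$windows
  s4 <- array(0, dim = c(n, m, length(w)))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      aln <- global_alignment_strings(genome1$seq[[i]], genome2$seq[[j]], ap)
      s4[i, j, ] <- s4_measure_multi(aln$aligned_x, aln$aligned_y, w,
                                     energy_table = params$energy_table,
                                     alpha = params$alpha)
    }
  }

  # row-major, genome 1 outer: pair (i, j) is row (i - 1) * m + j
  id1 <- rep(genome1$gene_id, each = m)
  id2 <- rep(genome2$gene_id, times = n)
  features <- cbind(S1 = as.vector(t(s1)), S2 = as.vector(t(s2)),
                    S3 = as.vector(t(s3)))
  for (k in seq_along(w))
    features <- cbind(features, as.vector(t(s4[, , k])))
  colnames(features) <- c("S1", "S2", "S3", paste0("S4_w", w))
  key <- paste(id1, id2, sep = "\r")
  lkey <- paste(labels$gene_id_1, labels$gene_id_2, sep = "\r")
  d <- as.integer(key %in% lkey)
  new_decision_system(data.frame(gene_id_1 = id1, gene_id_2 = id2,
                                 stringsAsFactors = FALSE),
                      features, d)
}

#' Class statistics of a decision system
#'
#' Counts, percentages and the imbalance ratio (IR = majority count /
#' minority count) of the non-ortholog (majority, d = 0) and ortholog
#' (minority, d = 1) classes. Percentages and IR print rounded half-up to
#' 3 decimals; the stored values are exact. IR is `NA` when the minority
#' class is empty.
#'
#' @param ds A `decision_system`.
#' @return An object of class `class_stats`: `n_major`, `n_minor`,
#'   `pct_major`, `pct_minor`, `ir`.
#' @export
class_stats <- function(ds) {
  stopifnot(inherits(ds, "decision_system"))
  class_stats_from_counts(sum(ds$d == 0L), sum(ds$d == 1L))
}

#' Class statistics from raw class counts
#'
#' @param n_major,n_minor Majority (non-ortholog) and minority (ortholog)
#'   class counts.
#' @return An object of class `class_stats`.
#' @export
class_stats_from_counts <- function(n_major, n_minor) {
  total <- n_major + n_minor
  if (total == 0) stop_format("empty decision system")
  structure(list(n_major = n_major, n_minor = n_minor,
                 pct_major = 100 * n_major / total,
                 pct_minor = 100 * n_minor / total,
                 ir = if (n_minor == 0) NA_real_ else n_major / n_minor),
            class = "class_stats")
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf("#Class (maj; min): (%d; %d)  %%Class: (%s; %s)  IR: %s\n",
              x$n_major, x$n_minor,
              format(round_half_up(x$pct_major, 3), nsmall = 3),
              format(round_half_up(x$pct_minor, 3), nsmall = 3),
              if (is.na(x$ir)) "undefined"
              else format(round_half_up(x$ir, 3), nsmall = 3)))
  invisible(x)
}

#' Train/test sizes of a fractional split
#'
#' The training size is `fraction * n_total` rounded half-up; the test
#' size is the remainder.
#'
#' @param n_total Number of pairs.
#' @param fraction Training fraction in (0, 1).
#' @return Named integer vector `c(train =, test =)`.
#' @export
split_sizes <- function(n_total, fraction) {
  if (!(fraction > 0 && fraction < 1))
    stop_format("fraction must be in (0, 1), got %g", fraction)
  tr <- round_half_up(fraction * n_total)
  c(train = as.integer(tr), test = as.integer(n_total - tr))
}

#' Random train/test split of a decision system
#'
#' A uniform random partition at the pair level (no stratification),
#' reproducible for a fixed seed. Train size is `round(fraction * n)`.
#'
#' @param ds A `decision_system`.
#' @param fraction Training fraction in (0, 1) (default 0.75).
#' @param seed Integer seed.
#' @return An object of class `train_test_split`: `train`, `test`
#'   (decision systems), `fraction`, `seed`.
#' @export
train_test_split <- function(ds, fraction = 0.75, seed = 42L) {
  stopifnot(inherits(ds, "decision_system"))
  sizes <- split_sizes(n_pairs(ds), fraction)
  idx <- with_seed(seed, sample.int(n_pairs(ds), sizes[["train"]]))
  structure(list(train = subset_pairs(ds, sort(idx)),
                 test = subset_pairs(ds, setdiff(seq_len(n_pairs(ds)), idx)),
                 fraction = fraction, seed = seed),
            class = "train_test_split")
}
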