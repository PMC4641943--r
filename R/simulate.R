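# Synthetic genome pairs with planted orthologs, and direct synthetic
# feature tables, so every stage of the pipeline can be exercised without
# external data. The generator emulates the regime the method targets:
# two related genomes whose true orthologs are a tiny fraction of all
# cross-genome pairs, ortholog sequences diverged by point substitutions,
# and block-structured synteny co-membership for ortholog pairs.

#' Parameters for the synthetic genome-pair generator
#'
#' @param n,m Gene counts of the two genomes (default 50 each, giving a
#'   2500-pair universe).
#' @param n_orth Number of planted ortholog pairs (default 5, IR = 499).
#' @param sub_rate Per-residue substitution probability applied
#'   independently on each ortholog copy (default 0.1).
#' @param mean_len Mean gene length in residues (default 200; lengths are
#'   gamma-distributed with a floor of 50).
#' @param n_blocks Number of locally collinear blocks (default 8).
#' @param indel_rate Per-residue insertion/deletion probability on
#'   ortholog copies (default 0: substitutions only).
#' @param bg_block_prob Probability that a background gene is placed in
#'   one random block (default 0.7).
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n = 50L, m = 50L, n_orth = 5L, sub_rate = 0.1,
                       mean_len = 200L, n_blocks = 8L, indel_rate = 0,
                       bg_block_prob = 0.7, seed = 42L) {
  stopifnot(n >= 1, m >= 1, n_orth >= 0, n_orth <= min(n, m),
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            mean_len >= 50, n_blocks >= 1)
  structure(list(n = as.integer(n), m = as.integer(m),
                 n_orth = as.integer(n_orth), sub_rate = sub_rate,
                 mean_len = mean_len, n_blocks = as.integer(n_blocks),
                 indel_rate = indel_rate, bg_block_prob = bg_block_prob,
                 seed = as.integer(seed)),
            class = "sim_params")
}

random_length <- function(k, mean_len) {
  pmax(50L, as.integer(round(rgamma(k, shape = 8, rate = 8 / mean_len))))
}

random_sequence <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, sub_rate, indel_rate) {
  res <- strsplit(seq, "")[[1]]
  hit <- runif(length(res)) < sub_rate
  if (any(hit)) {
    res[hit] <- vapply(res[hit], function(a)
      sample(setdiff(AA_ALPHABET, a), 1L), "")
  }
  if (indel_rate > 0) {
    keep <- runif(length(res)) >= indel_rate / 2
    if (!any(keep)) keep[1] <- TRUE
    res <- res[keep]
    ins <- runif(length(res)) < indel_rate / 2
    if (any(ins)) {
      out <- character(0)
      for (i in seq_along(res)) {
        out <- c(out, res[i])
        if (ins[i]) out <- c(out, sample(AA_ALPHABET, 1L))
      }
      res <- out
    }
  }
  paste(res, collapse = "")
}

#' Generate a synthetic genome pair with planted orthologs
#'
#' `n_orth` ancestral sequences are mutated independently into both
#' genomes (point substitutions at `sub_rate`, optional indels); the
#' remaining genes are unrelated background sequences. Each planted
#' ortholog pair shares a locally collinear block with at least one codon
#' on both sides; background genes are scattered over blocks at random.
#' The label table lists exactly the planted pairs. Byte-identical output
#' for a fixed seed.
#'
#' @param params A [sim_params()].
#' @return A list of class `pod_fixture`: `genome1`, `genome2`, `lcb`
#'   ([lcb_matrix()]), `labels` ([label_table()]), `params`.
#' @export
generate_genome_pair <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    n <- params$n; m <- params$m; k <- params$n_orth
    id1 <- sprintf("gA_%03d", seq_len(n))
    id2 <- sprintf("gB_%03d", seq_len(m))
    i_pos <- sample.int(n, k)
    j_pos <- sample.int(m, k)

    seqs1 <- character(n); seqs2 <- character(m)
    anc_len <- random_length(k, params$mean_len)
    for (t in seq_len(k)) {
      anc <- random_sequence(anc_len[t])
      seqs1[i_pos[t]] <- mutate_sequence(anc, params$sub_rate,
                                         params$indel_rate)
      seqs2[j_pos[t]] <- mutate_sequence(anc, params$sub_rate,
                                         params$indel_rate)
    }
    bg1 <- setdiff(seq_len(n), i_pos)
    bg2 <- setdiff(seq_len(m), j_pos)
    for (i in bg1) seqs1[i] <- random_sequence(random_length(1, params$mean_len))
    for (j in bg2) seqs2[j] <- random_sequence(random_length(1, params$mean_len))

    g1 <- genome("synthetic_A", id1, seqs1)
    g2 <- genome("synthetic_B", id2, seqs2)

    counts <- matrix(0L, params$n_blocks, n + m)
    codons <- function(L) max(1L, as.integer(round(L / 3)))
    for (t in seq_len(k)) {
      b <- sample.int(params$n_blocks, 1L)
      counts[b, i_pos[t]] <- codons(g1$length[i_pos[t]])
      counts[b, n + j_pos[t]] <- codons(g2$length[j_pos[t]])
    }
    for (i in bg1) if (runif(1) < params$bg_block_prob) {
      b <- sample.int(params$n_blocks, 1L)
      counts[b, i] <- codons(g1$length[i])
    }
    for (j in bg2) if (runif(1) < params$bg_block_prob) {
      b <- sample.int(params$n_blocks, 1L)
      counts[b, n + j] <- codons(g2$length[j])
    }

    structure(list(genome1 = g1, genome2 = g2,
                   lcb = lcb_matrix(counts, n, m),
                   labels = label_table(id1[i_pos], id2[j_pos]),
                   params = params),
              class = "pod_fixture")
  })
}

#' Write a synthetic fixture to disk
#'
#' Writes `genome1.fasta`, `genome2.fasta`, `lcb.tsv` and `labels.tsv`
#' into a directory.
#'
#' @param fixture A [generate_genome_pair()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "pod_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$genome1, file.path(dir, "genome1.fasta"))
  write_fasta(fixture$genome2, file.path(dir, "genome2.fasta"))
  write_lcb_matrix(fixture$lcb, file.path(dir, "lcb.tsv"),
                   c(fixture$genome1$gene_id, fixture$genome2$gene_id))
  write_labels(fixture$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Generate a synthetic feature table directly
#'
#' Bypasses sequence computation: 6-feature rows with the minority
#' (ortholog) class centred at `0.5 + separation/2` and the majority at
#' `0.5 - separation/2`, Gaussian noise truncated to \[0, 1\]. For direct
#' learner tests.
#'
#' @param n_major,n_minor Class sizes.
#' @param separation Distance between class centres in every feature.
#' @param noise Noise standard deviation.
#' @param seed Integer seed.
#' @return A `decision_system` (majority rows first).
#' @export
generate_feature_table <- function(n_major, n_minor, separation = 0.6,
                                   noise = 0.05, seed = 42L) {
  stopifnot(n_major >= 1, n_minor >= 1, separation >= 0, separation <= 1,
            noise >= 0)
  with_seed(seed, {
    mu_maj <- 0.5 - separation / 2
    mu_min <- 0.5 + separation / 2
    maj <- matrix(rnorm(6 * n_major, mu_maj, noise), n_major, 6)
    mnr <- matrix(rnorm(6 * n_minor, mu_min, noise), n_minor, 6)
    features <- pmin(pmax(rbind(maj, mnr), 0), 1)
    colnames(features) <- c("S1", "S2", "S3", "S4_w3", "S4_w5", "S4_w7")
    pairs <- data.frame(
      gene_id_1 = sprintf("x_%05d", seq_len(n_major + n_minor)),
      gene_id_2 = sprintf("y_%05d", seq_len(n_major + n_minor)),
      stringsAsFactors = FALSE)
    new_decision_system(pairs, features,
                        c(rep(0L, n_major), rep(1L, n_minor)))
  })
}
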