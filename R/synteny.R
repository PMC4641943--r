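# S3: similarity from shared membership of a gene pair in locally
# collinear blocks (LCBs), computed from the block x gene codon-count
# matrix. Genes in the same conserved segment are likely orthologs.

#' Blocks in which a gene pair has synteny evidence
#'
#' The qualifying blocks of pair `(i, j)` are those where gene i of
#' genome 1 or gene j of genome 2 (or both) contributes at least one
#' codon; their number is Q.
#'
#' @param lcb An [lcb_matrix()].
#' @param i Gene index in genome 1 (1..n).
#' @param j Gene index in genome 2 (1..m).
#' @return Integer vector of qualifying block indices (possibly empty).
#' @export
qualifying_blocks <- function(lcb, i, j) {
  stopifnot(inherits(lcb, "lcb_matrix"),
            i >= 1, i <= lcb$n, j >= 1, j <= lcb$m)
  which(lcb$counts[, i] >= 1 | lcb$counts[, lcb$n + j] >= 1)
}

#' Normalized codon-count distance of a pair within one block
#'
#' `|LCB[k, i] - LCB[k, n + j]|` divided by the range of row k over all
#' n + m gene columns; 0 when the row is constant (zero range).
#'
#' @param lcb An [lcb_matrix()].
#' @param k Block index.
#' @param i,j Gene indices in genomes 1 and 2.
#' @return A value in \[0, 1\].
#' @export
block_distance <- function(lcb, k, i, j) {
  stopifnot(inherits(lcb, "lcb_matrix"), k >= 1, k <= nrow(lcb$counts))
  row <- lcb$counts[k, ]
  rng <- max(row) - min(row)
  if (rng == 0) return(0)
  abs(row[i] - row[lcb$n + j]) / rng
}

#' S3: synteny similarity of a gene pair
#'
#' One minus the mean [block_distance()] over the qualifying blocks only;
#' blocks where neither gene appears are excluded. A pair with no
#' qualifying block (Q = 0, no synteny evidence) scores 0.
#'
#' @param lcb An [lcb_matrix()].
#' @param i,j Gene indices in genomes 1 and 2.
#' @return A value in \[0, 1\].
#' @export
s3_measure <- function(lcb, i, j) {
  q <- qualifying_blocks(lcb, i, j)
  if (length(q) == 0L) return(0)
  d <- vapply(q, function(k) block_distance(lcb, k, i, j), 0)
  1 - mean(d)
}

# All-pairs S3 as an n x m matrix (vectorized over blocks).
s3_all <- function(lcb) {
  counts <- lcb$counts
  n <- lcb$n; m <- lcb$m
  rng <- apply(counts, 1, max) - apply(counts, 1, min)
  out <- matrix(0, n, m)
  c1 <- counts[, seq_len(n), drop = FALSE]
  c2 <- counts[, n + seq_len(m), drop = FALSE]
  for (i in seq_len(n)) {
    # blocks x m: distance of (i, j) in every block, 0 on constant rows
    diff <- abs(c1[, i] - c2)
    d <- sweep(diff, 1, pmax(rng, 1), "/")
    d[rng == 0, ] <- 0
    qual <- (c1[, i] >= 1) | (c2 >= 1)
    qn <- colSums(qual)
    s <- colSums(d * qual)
    out[i, ] <- ifelse(qn == 0, 0, 1 - s / pmax(qn, 1))
  }
  out
}
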