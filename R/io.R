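# Readers and writers for the formats the tool touches: protein FASTA,
# the LCB codon-count matrix (TSV), the curated ortholog label table (TSV)
# and the computed feature table (TSV). Parsing and validation only.

#' Construct a genome from gene ids and residue strings
#'
#' A genome is an ordered collection of protein-coding genes, each with a
#' unique id and an upper-case amino-acid sequence over the 20-letter
#' alphabet (no gaps, no ambiguity codes).
#'
#' @param name Genome name (free text).
#' @param gene_ids Character vector of unique gene ids.
#' @param sequences Character vector of residue strings, same length.
#' @return An object of class `genome` with elements `name`, `gene_id`,
#'   `seq` (named by gene id) and `length` (residue counts).
#' @export
genome <- function(name, gene_ids, sequences) {
  if (length(gene_ids) == 0L) stop_format("genome '%s' has no genes", name)
  if (length(gene_ids) != length(sequences))
    stop_format("gene_ids and sequences differ in length")
  if (anyDuplicated(gene_ids))
    stop_format("duplicate gene id(s): %s",
                paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sequences <- toupper(sequences)
  nc <- nchar(sequences)
  if (any(nc == 0L))
    stop_format("empty sequence for gene(s): %s",
                paste(gene_ids[nc == 0L], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequences)
  if (any(bad))
    stop_format("non-amino-acid character in gene(s): %s",
                paste(gene_ids[bad], collapse = ", "))
  structure(list(name = name, gene_id = gene_ids,
                 seq = stats::setNames(sequences, gene_ids),
                 length = stats::setNames(as.integer(nc), gene_ids)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s': %d genes, residue lengths %d-%d>\n",
              x$name, length(x$gene_id), min(x$length), max(x$length)))
  invisible(x)
}

#' Read a protein FASTA file as a genome
#'
#' The gene id is the header token before the first whitespace; the rest of
#' the description line is ignored. Sequences must be non-empty amino-acid
#' strings over the 20-letter alphabet; `*` and ambiguity codes are
#' rejected with the offending record named.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param name Genome name; defaults to the file name without extension.
#' @return A [genome()] object, record order preserved.
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_format("no FASTA records in %s", path)
  ids <- sub("\\s.*$", "", names(set))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genome(name, ids, as.character(set))
}

#' Write a genome to a FASTA file
#'
#' @param g A [genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  out <- paste0(">", g$gene_id, "\n", g$seq)
  writeLines(out, path)
  invisible(path)
}

#' Construct a locally-collinear-block (LCB) codon-count matrix
#'
#' Rows are conserved blocks, columns are genes: the first `n` columns are
#' genome 1's genes in order, the next `m` columns genome 2's. Entry
#' `(k, p)` is the number of codons gene `p` contributes to block `k`.
#'
#' @param counts Integer matrix, blocks x (n + m), all entries >= 0.
#' @param n,m Number of genes in genomes 1 and 2.
#' @return An object of class `lcb_matrix`.
#' @export
lcb_matrix <- function(counts, n, m) {
  counts <- as.matrix(counts)
  if (ncol(counts) != n + m)
    stop_format("LCB matrix has %d columns; expected n + m = %d",
                ncol(counts), n + m)
  if (any(counts < 0)) stop_format("negative codon count in LCB matrix")
  if (any(counts != floor(counts)))
    stop_format("non-integer codon count in LCB matrix")
  structure(list(counts = counts, n = as.integer(n), m = as.integer(m)),
            class = "lcb_matrix")
}

#' @export
print.lcb_matrix <- function(x, ...) {
  cat(sprintf("<lcb_matrix: %d blocks x (%d + %d) genes>\n",
              nrow(x$counts), x$n, x$m))
  invisible(x)
}

#' Read an LCB codon-count matrix from TSV
#'
#' The header row must contain every gene id of `genome1` followed by every
#' gene id of `genome2`; each subsequent row is one block of non-negative
#' integer codon counts. Columns may appear in any order within the file;
#' they are rearranged to genome1-then-genome2 order.
#'
#' @param path Path to a tab-separated file.
#' @param genome1,genome2 The two [genome()]s the columns refer to.
#' @return An [lcb_matrix()].
#' @export
read_lcb_matrix <- function(path, genome1, genome2) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  tab <- read.delim(path, check.names = FALSE, sep = "\t")
  want <- c(genome1$gene_id, genome2$gene_id)
  missing <- setdiff(want, colnames(tab))
  if (length(missing))
    stop_format("LCB matrix is missing gene column(s): %s",
                paste(missing, collapse = ", "))
  counts <- as.matrix(tab[, want, drop = FALSE])
  if (!is.numeric(counts)) stop_format("non-numeric entry in LCB matrix")
  lcb_matrix(counts, length(genome1$gene_id), length(genome2$gene_id))
}

#' Write an LCB matrix to TSV
#'
#' @param lcb An [lcb_matrix()].
#' @param path Output path.
#' @param gene_ids Column names: ids of genome 1 then genome 2.
#' @return Invisibly, `path`.
#' @export
write_lcb_matrix <- function(lcb, path, gene_ids) {
  stopifnot(inherits(lcb, "lcb_matrix"), length(gene_ids) == lcb$n + lcb$m)
  df <- as.data.frame(lcb$counts)
  colnames(df) <- gene_ids
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a curated ortholog label table
#'
#' A two-column TSV of gene-id pairs (genome 1 id, genome 2 id), no header.
#' Duplicate lines collapse to one pair (set semantics).
#'
#' @param path Path to the TSV.
#' @return A data.frame of class `label_table` with columns `gene_id_1`,
#'   `gene_id_2`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop_format("malformed label line %d: expected two tab-separated ids",
                which(nf < 2L)[1L])
  df <- data.frame(gene_id_1 = vapply(parts, `[[`, "", 1L),
                   gene_id_2 = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  label_table(df$gene_id_1, df$gene_id_2)
}

#' Construct a label table of curated ortholog pairs
#'
#' @param gene_id_1,gene_id_2 Paired id vectors (genome 1, genome 2).
#' @return A data.frame of class `label_table`.
#' @export
label_table <- function(gene_id_1 = character(), gene_id_2 = character()) {
  df <- unique(data.frame(gene_id_1 = as.character(gene_id_1),
                          gene_id_2 = as.character(gene_id_2),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("label_table", "data.frame")
  df
}

#' Write a label table to TSV
#'
#' @param labels A [label_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a decision system's feature table to TSV
#'
#' Columns: `gene_id_1`, `gene_id_2`, one column per feature (S1, S2, S3,
#' S4_w3, S4_w5, S4_w7 by default) and the decision `d`. Feature values are
#' serialized with 9 decimal digits so a round-trip read reproduces them.
#'
#' @param ds A [build_decision_system()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(ds, path) {
  stopifnot(inherits(ds, "decision_system"))
  feat <- apply(ds$features, 2, function(col) sprintf("%.9f", col))
  if (nrow(ds$pairs) == 1L) feat <- matrix(feat, nrow = 1L,
                                           dimnames = list(NULL, colnames(ds$features)))
  if (nrow(ds$pairs) == 0L)
    feat <- matrix(character(), nrow = 0L, ncol = ncol(ds$features),
                   dimnames = list(NULL, colnames(ds$features)))
  df <- cbind(ds$pairs, as.data.frame(feat, stringsAsFactors = FALSE),
              d = ds$d)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the TSV.
#' @return A `decision_system`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, sep = "\t",
                   colClasses = "character")
  need <- c("gene_id_1", "gene_id_2", "d")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop_format("feature table missing column(s): %s",
                paste(missing, collapse = ", "))
  feat_cols <- setdiff(colnames(df), need)
  features <- as.matrix(as.data.frame(lapply(df[feat_cols], as.numeric)))
  colnames(features) <- feat_cols
  new_decision_system(df[c("gene_id_1", "gene_id_2")], features,
                      as.integer(df$d))
}
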