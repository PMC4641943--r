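# Alignment-based similarity: raw Smith-Waterman / Needleman-Wunsch scores
# with affine gaps, corpus-wide normalization maxima, and the S1 and S2
# measures. The dynamic-programming kernel lives in src/align.cpp; the
# substitution matrices are the pinned NCBI tables shipped with Biostrings.

#' Alignment parameters (substitution matrix and affine gap penalties)
#'
#' A gap of length L costs `gap_open + L * gap_extend`: the first gap
#' residue pays both the opening and the extension penalty.
#'
#' @param matrix_name One of `"BLOSUM50"`, `"BLOSUM62"`, `"PAM250"`.
#' @param gap_open Gap-opening penalty (GOP), positive.
#' @param gap_extend Gap-extension penalty (GEP), positive, `<= gap_open`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix_name = c("BLOSUM50", "BLOSUM62", "PAM250"),
                             gap_open, gap_extend) {
  matrix_name <- match.arg(matrix_name)
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop_format("require gap_open >= gap_extend > 0 (got %g, %g)",
                gap_open, gap_extend)
  structure(list(matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = substitution_matrix(matrix_name)),
            class = "alignment_params")
}

#' Named alignment parameter presets
#'
#' Four standard substitution-matrix / gap-penalty combinations spanning a
#' wide range of amino-acid identity levels:
#' `blosum50` (BLOSUM50, 15/8), `blosum621` (BLOSUM62, 8/7),
#' `blosum622` (BLOSUM62, 12/6), `pam250` (PAM250, 10/8).
#'
#' @param name Preset name.
#' @return An [alignment_params()].
#' @export
alignment_preset <- function(name = c("blosum50", "blosum621", "blosum622",
                                      "pam250")) {
  name <- match.arg(name)
  switch(name,
    blosum50  = alignment_params("BLOSUM50", 15, 8),
    blosum621 = alignment_params("BLOSUM62", 8, 7),
    blosum622 = alignment_params("BLOSUM62", 12, 6),
    pam250    = alignment_params("PAM250", 10, 8))
}

# Fetch a pinned substitution matrix from Biostrings' data sets.
substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Raw local and global alignment scores for one sequence pair
#'
#' Local is the optimal Smith-Waterman score (floored at 0 by the empty
#' alignment); global is the optimal Needleman-Wunsch score with penalized
#' end gaps, which may be negative. Both use the same affine gap model and
#' are symmetric in the two sequences.
#'
#' @param x,y Residue strings (or single-gene [genome()] entries).
#' @param params An [alignment_params()].
#' @return A list of class `score_pair`: `local_score`, `global_score`.
#' @export
raw_alignment_scores <- function(x, y, params) {
  stopifnot(inherits(params, "alignment_params"))
  loc <- .aln_cross_scores(x, y, params$matrix, params$gap_open,
                           params$gap_extend, TRUE)[1, 1]
  glo <- .aln_cross_scores(x, y, params$matrix, params$gap_open,
                           params$gap_extend, FALSE)[1, 1]
  structure(list(local_score = loc, global_score = glo), class = "score_pair")
}

#' All-pairs local and global score matrices for two genomes
#'
#' @param genome1,genome2 [genome()] objects (n and m genes).
#' @param params An [alignment_params()].
#' @return A list with `local` and `global` n x m score matrices
#'   (rows genome 1, columns genome 2).
#' @export
cross_alignment_scores <- function(genome1, genome2, params) {
  stopifnot(inherits(genome1, "genome"), inherits(genome2, "genome"),
            inherits(params, "alignment_params"))
  loc <- .aln_cross_scores(unname(genome1$seq), unname(genome2$seq),
                           params$matrix, params$gap_open,
                           params$gap_extend, TRUE)
  glo <- .aln_cross_scores(unname(genome1$seq), unname(genome2$seq),
                           params$matrix, params$gap_open,
                           params$gap_extend, FALSE)
  dimnames(loc) <- dimnames(glo) <- list(genome1$gene_id, genome2$gene_id)
  list(local = loc, global = glo)
}

#' Global (Needleman-Wunsch) alignment strings for one pair
#'
#' Deterministic traceback: ties prefer the diagonal, then a gap in the
#' second sequence, then a gap in the first.
#'
#' @param x,y Residue strings.
#' @param params An [alignment_params()].
#' @return A list: `score`, `aligned_x`, `aligned_y` (equal-length gapped
#'   strings, gap symbol `-`).
#' @export
global_alignment_strings <- function(x, y, params) {
  stopifnot(inherits(params, "alignment_params"))
  .aln_global_traceback(x, y, params$matrix, params$gap_open,
                        params$gap_extend)
}

#' Normalization maxima over the full genome cross-product
#'
#' The maxima of the raw local and global scores over every pair
#' `(k, p)`, k in genome 1, p in genome 2; the pair being scored is itself
#' among them. `max_local` must be positive or S1 is undefined for the
#' corpus.
#'
#' @param genome1,genome2 [genome()]s, or pass `scores =` a precomputed
#'   [cross_alignment_scores()] result to avoid realigning.
#' @param params An [alignment_params()].
#' @param scores Optional precomputed score matrices.
#' @return A list of class `normalization_constants`: `max_local`,
#'   `max_global`.
#' @export
compute_normalization <- function(genome1, genome2, params, scores = NULL) {
  if (is.null(scores)) scores <- cross_alignment_scores(genome1, genome2, params)
  max_local <- max(scores$local)
  max_global <- max(scores$global)
  if (max_local <= 0)
    stop_format("degenerate corpus: maximum local score is %g (<= 0); S1 undefined",
                max_local)
  structure(list(max_local = max_local, max_global = max_global),
            class = "normalization_constants")
}

#' S1: averaged, normalized local and global alignment similarity
#'
#' Each raw score is divided by the corpus-wide maximum of its kind and
#' clipped to 0 when non-positive; S1 is the mean of the two clipped
#' components, in \[0, 1\]. When the global maximum itself is non-positive
#' the global component is 0 for every pair.
#'
#' @param scores A [raw_alignment_scores()] result (or a list with
#'   `local_score`, `global_score`; vectors allowed).
#' @param norm A [compute_normalization()] result.
#' @return S1 value(s) in \[0, 1\].
#' @export
s1_measure <- function(scores, norm) {
  stopifnot(inherits(norm, "normalization_constants"))
  cl <- scores$local_score / norm$max_local
  sl <- pmax(cl, 0)
  if (norm$max_global <= 0) {
    sg <- rep(0, length(sl))
  } else {
    sg <- pmax(scores$global_score / norm$max_global, 0)
  }
  (sl + sg) / 2
}

#' S2: normalized sequence-length similarity
#'
#' `1 - |L(x) - L(y)| / (Lmax - Lmin)` where the extremes are taken over
#' the union of both genomes' gene lengths. Equals 1 iff the lengths are
#' equal; when every gene in the corpus has the same length the measure is
#' defined as 1 (identical lengths are maximally similar).
#'
#' @param Lx,Ly Lengths of the paired genes (vectors allowed).
#' @param Lmin,Lmax Minimum and maximum gene length over both genomes.
#' @return S2 value(s) in \[0, 1\].
#' @export
s2_length_measure <- function(Lx, Ly, Lmin, Lmax) {
  stopifnot(Lmin <= Lmax)
  if (any(Lx < Lmin | Lx > Lmax | Ly < Lmin | Ly > Lmax))
    stop_format("lengths outside [Lmin, Lmax]")
  if (Lmax == Lmin) return(rep(1, length(Lx)))
  1 - abs(Lx - Ly) / (Lmax - Lmin)
}
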