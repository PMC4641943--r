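# Independent oracles used across the suite. The alignment oracle is a
# plain-R three-state recursion (affine gaps: a gap of length L costs
# go + L * ge), written separately from the package's compiled kernel.

gotoh_oracle <- function(x, y, mat, go, ge, type = c("global", "local")) {
  type <- match.arg(type)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  n <- length(xs); m <- length(ys)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  local <- type == "local"
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(go + (i - 1) * ge)
  for (j in 2:(m + 1)) Iy[1, j] <- -(go + (j - 1) * ge)
  if (local) { M[, 1] <- 0; M[1, ] <- 0 }
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[xs[i - 1], ys[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    if (local) M[i, j] <- max(M[i, j], s)
    Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
    Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
    if (local) best <- max(best, M[i, j])
  }
  if (local) best else max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

random_protein <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "K")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Tiny genome of random proteins for cross-product checks.
random_genome <- function(name, k, len_range = c(5, 12)) {
  genome(name, sprintf("%s_%02d", name, seq_len(k)),
         vapply(seq_len(k), function(i)
           random_protein(sample(len_range[1]:len_range[2], 1),
                          alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                              "")[[1]]), ""))
}

# Direct Pearson r / two-sided p oracle via stats::cor.test.
cor_sig_oracle <- function(mx, my, alpha = 0.05) {
  if (length(mx) < 3 || stats::sd(mx) == 0 || stats::sd(my) == 0) return(0)
  ct <- suppressWarnings(stats::cor.test(mx, my, method = "pearson"))
  r <- unname(ct$estimate)
  if (is.na(r) || r <= 0 || ct$p.value > alpha) return(0)
  r
}

blosum50 <- function() {
  env <- new.env(); utils::data("BLOSUM50", package = "Biostrings", envir = env)
  get("BLOSUM50", envir = env)
}
blosum62 <- function() {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
}
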