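# S4: physicochemical-profile similarity. Residues of the gapless regions
# of a global alignment are mapped to contact energies, smoothed by a
# moving average of window W, and the two spectra are compared by Pearson
# correlation; significant positive correlations are aggregated weighted
# by region length.

#' Read a per-residue energy table
#'
#' Two-column TSV (`residue`, `energy`) covering all 20 amino acids.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of length 20.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("residue", "energy") %in% colnames(df)))
    stop_format("energy table needs columns 'residue' and 'energy'")
  tab <- stats::setNames(as.numeric(df$energy), df$residue)
  missing <- setdiff(AA_ALPHABET, names(tab))
  if (length(missing))
    stop_format("energy table missing residue(s): %s",
                paste(missing, collapse = ", "))
  tab[AA_ALPHABET]
}

#' Default contact-energy table
#'
#' Per-residue effective contact (partition) energies derived from the
#' Miyazawa-Jernigan residue-contact statistics, shipped with the package.
#' Any 20-residue scale can be substituted via [read_energy_table()].
#'
#' @return Named numeric vector of length 20.
#' @export
default_energy_table <- function() {
  read_energy_table(system.file("extdata", "mj_contact_energies.tsv",
                                package = "orthopair", mustWork = TRUE))
}

#' Maximal gapless regions of a global alignment
#'
#' Scans the aligned columns and returns every maximal run in which
#' neither sequence has a gap, in order.
#'
#' @param aligned_x,aligned_y Equal-length gapped strings (gap `-`).
#' @return List of regions, each a list with `res_x`, `res_y`, `length`.
#' @export
extract_gapless_regions <- function(aligned_x, aligned_y) {
  if (nchar(aligned_x) != nchar(aligned_y))
    stop_format("aligned strings differ in length (%d vs %d)",
                nchar(aligned_x), nchar(aligned_y))
  cx <- strsplit(aligned_x, "")[[1]]
  cy <- strsplit(aligned_y, "")[[1]]
  ok <- cx != "-" & cy != "-"
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(b) {
    span <- starts[b]:ends[b]
    list(res_x = paste(cx[span], collapse = ""),
         res_y = paste(cy[span], collapse = ""),
         length = length(span))
  })
}

#' Moving average of a numeric series
#'
#' Sliding-window mean of window `W`; output length `len - W + 1`, or an
#' empty spectrum when the series is shorter than the window.
#'
#' @param series Numeric vector.
#' @param W Window size, >= 1.
#' @return Numeric vector (possibly empty).
#' @export
moving_average <- function(series, W) {
  stopifnot(W >= 1)
  n <- length(series)
  if (n < W) return(numeric(0))
  cs <- cumsum(c(0, series))
  (cs[(W + 1):(n + 1)] - cs[1:(n - W + 1)]) / W
}

#' Correlation similarity of two spectra
#'
#' Pearson r of the two moving-average spectra, retained only when the
#' two-sided significance of r is at most `alpha` and r is positive;
#' otherwise 0. Spectra shorter than 3 points or with zero variance
#' cannot be tested and score 0.
#'
#' @param mx,my Equal-length numeric spectra.
#' @param alpha Significance level (default 0.05).
#' @return A value in \[0, 1\].
#' @export
region_similarity <- function(mx, my, alpha = 0.05) {
  if (length(mx) != length(my))
    stop_format("spectra differ in length (%d vs %d)", length(mx), length(my))
  if (length(mx) < 3L) return(0)
  if (stats::sd(mx) == 0 || stats::sd(my) == 0) return(0)
  n <- length(mx)
  r <- min(1, max(-1, stats::cor(mx, my)))
  if (is.na(r) || r <= 0) return(0)
  # two-sided significance via the t transform with n - 2 df
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  if (p > alpha) return(0)
  r
}

#' S4: spectral physicochemical similarity of an aligned pair
#'
#' Each gapless region's residues are replaced by contact energies and
#' smoothed with a moving average of window `W`; the region similarity is
#' the significant positive Pearson correlation of the two spectra. S4 is
#' the length-weighted mean over all gapless regions: regions too short
#' to yield a testable spectrum contribute 0 to the numerator but their
#' length still counts in the denominator. 0 if there are no gapless
#' regions.
#'
#' @param aligned_x,aligned_y Equal-length gapped strings from a global
#'   alignment.
#' @param W Moving-average window size.
#' @param energy_table Named numeric vector over the 20 residues
#'   (default [default_energy_table()]).
#' @param alpha Significance level for the correlation (default 0.05).
#' @return A value in \[0, 1\].
#' @export
s4_measure <- function(aligned_x, aligned_y, W,
                       energy_table = default_energy_table(),
                       alpha = 0.05) {
  s4_measure_multi(aligned_x, aligned_y, W, energy_table, alpha)[[1]]
}

# Vectorized over window sizes: regions and energy mapping are shared.
s4_measure_multi <- function(aligned_x, aligned_y, windows,
                             energy_table, alpha = 0.05) {
  regions <- extract_gapless_regions(aligned_x, aligned_y)
  out <- stats::setNames(numeric(length(windows)),
                         paste0("S4_w", windows))
  if (length(regions) == 0L) return(out)
  total <- sum(vapply(regions, `[[`, 0L, "length"))
  for (reg in regions) {
    ex <- unname(energy_table[strsplit(reg$res_x, "")[[1]]])
    ey <- unname(energy_table[strsplit(reg$res_y, "")[[1]]])
    if (anyNA(ex) || anyNA(ey))
      stop_format("residue missing from energy table")
    for (k in seq_along(windows)) {
      r <- region_similarity(moving_average(ex, windows[k]),
                             moving_average(ey, windows[k]), alpha = alpha)
      out[k] <- out[k] + r * reg$length
    }
  }
  out / total
}
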