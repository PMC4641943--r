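---
title: "Methods: supervised pairwise ortholog detection with orthopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised pairwise ortholog detection with orthopair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`orthopair` frames pairwise ortholog detection (POD) between two
annotated proteomes `G1 = {x_1..x_n}` and `G2 = {y_1..y_m}` as binary
classification of the full cross-product universe
`U = {(x_i, y_j)}`. Each pair carries six attributes in `[0, 1]` plus a
curated decision `d` (1 = ortholog). The attributes combine four kinds
of evidence, each of which fails in a different way and therefore
complements the others:

**S1, alignment.** Smith–Waterman local and Needleman–Wunsch global
scores with affine gaps (a gap of length `L` costs `go + L·ge`; the
first gap residue pays both penalties). Each raw score is divided by
the maximum of its kind over *all* `n × m` pairs — the quantifier is
unrestricted, so the pair being scored is included in its own
normalization — and clipped to 0 when non-positive; S1 is the mean of
the two components. The local score already floors at 0 (the empty
alignment); the global score can be negative, hence the clip. If the
corpus-wide *global* maximum is itself non-positive, the global
component is 0 for every pair; if the *local* maximum is non-positive
the corpus contains no positively scoring pair at all and S1 is
reported as undefined (an error) rather than silently zeroed.

**S2, length.** `1 − |L(x_i) − L(y_j)| / (Lmax − Lmin)`, with the
extremes over the union of both genomes. Insertions and deletions
accumulate over evolutionary time, so related genes tend to have
similar lengths. If every gene in the corpus has the same length the
formula is 0/0; we define S2 = 1 there, the limit as the numerator
vanishes faster than the denominator (identical lengths are maximally
similar).

**S3, synteny.** From a blocks × genes matrix of codon counts in
locally collinear blocks (LCBs) — conserved, rearrangement-free
segments, produced upstream by a whole-genome aligner and consumed here
as an explicit input file. For a pair, the qualifying blocks `Q` are
those where at least one of the two genes has at least one codon; S3 is
one minus the mean, over qualifying blocks only, of
`|LCB[k,i] − LCB[k,n+j]|` normalized by the row's range. Two
conventions close the formula's degenerate corners: a constant block
row (range 0) contributes distance 0, and a pair with no qualifying
block (Q = 0, no synteny evidence at all) scores S3 = 0, the minimum.
Restricting the mean to qualifying blocks and dividing by Q is
equivalent to summing zeros over non-qualifying blocks; we exclude them
explicitly.

**S4 (windows 3, 5, 7), physicochemical profile.** The global (NW)
alignment computed for S1 — same matrix and penalties, one
deterministic traceback — is scanned for maximal gapless regions. In
each region both residue strings are mapped to per-residue contact
energies and smoothed with a moving average of window `W`; the region's
similarity is the Pearson correlation of the two spectra, kept only
when positive and significant (two-sided p ≤ 0.05 via the
`t = r·sqrt((n−2)/(1−r²))` transform with `n − 2` degrees of freedom),
else 0. S4 aggregates region similarities weighted by region length;
the denominator is the total gapless length, so regions too short to
test (spectra under 3 points) or with zero variance dilute the score
rather than being dropped. This captures periodicity of physicochemical
properties that survives even when amino-acid identity is low. Three
design points deserve note: (i) significant *negative* correlations are
clamped to 0 — S4 is a similarity combined with the other measures and
anticorrelation is not similarity; (ii) the spectral representation is
the moving average only, no autoregressive coefficients; (iii) the
default energy table is a per-residue effective contact (partition)
energy scale derived from the Miyazawa–Jernigan residue-contact
statistics, shipped as a plain TSV and overridable — the measure's
mathematics is table-agnostic.

## Imbalanced learning

True orthologs are a vanishing minority of `U` (imbalance ratios from
hundreds at desk scale to ~10⁴ for real proteome pairs), so the
package trains with explicit imbalance treatments:

- **ROS** (random oversampling): minority rows are replicated by seeded
  sampling with replacement until the minority count equals
  `round(RS/100 × majority count)`. RS = 100 balances the classes;
  RS = 130 overshoots by 30%. Majority rows and all original minority
  rows are never altered or dropped; if the target is below the current
  minority count nothing is removed.
- **Cost-sensitive weighting**: instance weights `C(+|−) = IR`,
  `C(−|+) = 1`, giving both classes equal total mass. The weights enter
  the random forest's split impurity and leaf decisions.
- **Linear SVM**: minimizes `λ/2‖w‖² + mean hinge` by subgradient
  descent, step `step_size/√t`, 100 iterations, full batch by default
  (deterministic). The L2 step is applied in proximal (implicit) form
  `w ← (w − η∇loss)/(1 + ηλ)`, which is stable for any λ including the
  unregularized preset λ = 0 and arbitrarily large values. An
  unregularized intercept is fitted: the six features are all
  non-negative, so both class centroids lie in the positive orthant and
  no homogeneous hyperplane could separate them. The contract is the
  optimization objective, not a particular solver.
- **Random forest**: `n_trees` CART-style trees (default 100) on
  bootstrap samples with `attrs_per_node` candidate features per split
  (default 3 = `int(log2(6) + 1)`), majority vote, fixed seed and a
  single thread for determinism. The forest machinery is provided by
  `ranger`; ties within a tree are resolved by the seeded RNG, so
  results are deterministic given the seed.

Evaluation uses the confusion matrix with ortholog = positive:
`G-Mean = sqrt(sensitivity × specificity)` and the rate-based
approximation `AUC = (1 + TPrate − FPrate)/2` — the area under the
single-point ROC of a hard classifier, not a score-ranking integral. A
predictor that never finds an ortholog has sensitivity 0 and G-Mean 0,
with no smoothing. Both metrics require both classes in the truth; an
empty class is an error, not a 0. By AM–GM, G-Mean ≤ AUC always.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| substitution matrix, `go`/`ge` | BLOSUM50, 15/8 | presets `blosum50` (15/8), `blosum621` (BLOSUM62 8/7), `blosum622` (BLOSUM62 12/6), `pam250` (10/8); score units of the matrix |
| `windows` | 3, 5, 7 | S4 moving-average window sizes (residues) |
| `alpha` | 0.05 | two-sided significance level of the S4 correlation |
| `fraction` | 0.75 | training share of the random pair-level split |
| `rs_percent` | 100 | ROS target minority size as % of majority |
| `reg_param` | 0.5 | SVM λ; presets 1.0 / 0.5 / 0.0 |
| `n_trees`, `attrs_per_node` | 100, 3 | forest size and per-split feature draw |

The split is a plain uniform partition, not stratified: with realistic
imbalance the minority survives in expectation, and at desk scale a
25% partition may legitimately contain zero orthologs — aggregate
confusion counts over seeds when that matters (as the acceptance
script does).

## The synthetic generator

`generate_genome_pair()` emulates the regime the method targets:
`n_orth` ancestral proteins are mutated independently into both genomes
by point substitutions at `sub_rate` (uniform background frequencies
over the 20 residues; optional indels via `indel_rate`, kept separate
so the gapless-region logic of S4 can be exercised in isolation);
remaining genes are unrelated random sequences. Gene lengths are
gamma-distributed (shape 8) around `mean_len` with a floor of 50
residues; the default of 200 keeps a 50 × 50 universe comfortably
interactive while leaving hundreds of alignment columns per pair. Each
planted pair shares one LCB with ~length/3 codons on both sides;
background genes are placed in one random block with probability 0.7.
Defaults (n = m = 50, 5 orthologs, sub_rate 0.1, 8 blocks) give a
2500-pair universe at IR 499.

What the generator does **not** emulate: realistic codon/rate models,
gene duplications and whole-genome duplication (so no hard paralogy
traps), domain shuffling, block rearrangements, or biased amino-acid
composition. Passing the recovery tests therefore shows the pipeline is
internally correct and that the features separate planted homology from
noise — it does not certify performance on real WGD-affected proteomes,
where curated labels and upstream LCB computation carry real
uncertainty.

`generate_feature_table()` skips sequences entirely and draws the six
features from truncated Gaussians around class centres
`0.5 ± separation/2`; it exists to test learners and metrics directly.

## Numerical choices

- Alignment ties in the global traceback prefer diagonal, then a gap in
  the second sequence, then in the first — aligned strings are
  deterministic. The DP kernel is compiled (Rcpp); its scores are
  checked in the test suite against both a plain-R affine-gap recursion
  and `Biostrings::pairwiseAlignment` on random pairs.
- Feature tables serialize floats with 9 decimals for bit-stable
  round-trips.
- Printed percentages and imbalance ratios round half-up to 3 decimals,
  matching how such tables are conventionally reported; stored values
  are exact.
- Train size is `round(fraction × |U|)` (half-up); seeds are explicit
  everywhere randomness exists (splits, ROS, minibatches, forests,
  generators) with default 42, and the caller's RNG state is always
  restored.
- Problem sizes used by the shipped checks: oracle equivalence on
  sequences ≤ 8 residues; feature-level oracles on 3 × 4 to 12 × 12
  genomes; recovery experiments on five 50 × 50 fixtures.

## Known limitations

- S1 normalization constants are corpus-relative: each decision system
  (genome pair × alignment preset) has its own maxima, so feature
  values are not comparable across corpora, although a trained model
  can still be *applied* to any system with the same six-attribute
  schema (the cross-pair transfer setting).
- The rate-based AUC of a hard classifier is coarser than a
  score-based ROC area; it is used deliberately for comparability
  across learners that do not emit calibrated scores.
- LCB computation is out of scope: the codon-count matrix is an input,
  and its quality bounds S3.
- Model persistence is not implemented; the CLI `run` command trains
  and evaluates in one process. Refit from the feature table (seconds
  at desk scale) rather than serializing models.
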