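# orthopair

Supervised pairwise ortholog detection (POD) with imbalance-aware
learning.

## The problem

Orthologs are genes in different species that descend by speciation from
a single ancestral gene; telling them apart from paralogs and unrelated
genes is the first step of most comparative-genomics analyses. Classical
pairwise detectors (reciprocal best hits and relatives) rely on sequence
similarity alone and are easily misled in lineages with rampant
paralogy, e.g. yeasts that underwent whole-genome duplication.

`orthopair` instead treats POD as a supervised binary classification of
**every** cross-genome gene pair. For genomes `G1 = {x_1..x_n}` and
`G2 = {y_1..y_m}` it builds a decision system `DS = (U, A ∪ {d})` over
the universe `U` of all `n × m` pairs, with six similarity attributes
per pair:

- **S1** — the mean of the Smith–Waterman local and Needleman–Wunsch
  global alignment scores (affine gaps, BLOSUM/PAM matrices), each
  normalized by its maximum over all `n × m` pairs and clipped at 0:
  `S1 = (Sl + Sg) / 2`.
- **S2** — normalized length similarity
  `1 − |L(x) − L(y)| / (Lmax − Lmin)`, extremes over both genomes.
- **S3** — synteny: one minus the mean range-normalized codon-count
  difference of the pair over the locally collinear blocks (LCBs) in
  which at least one of the two genes appears.
- **S4 (W = 3, 5, 7)** — physicochemical profile: residues of the
  gapless regions of the global alignment are mapped to contact
  energies, smoothed by a moving average of window `W`, and compared by
  Pearson correlation; significant positive correlations are aggregated
  weighted by region length.

Because true orthologs are a tiny minority (imbalance ratios in the
thousands for real genome pairs), plain classifiers degenerate into
predicting "non-ortholog" everywhere. The package provides random
oversampling (ROS, to a target resampling size RS%), cost-sensitive
instance weighting with `C(+|−) = IR`, a linear hinge-loss SVM and a
random forest, and scores models with imbalance-aware metrics:

```
G-Mean = sqrt(sensitivity × specificity)
AUC    = (1 + TPrate − FPrate) / 2
```

A synthetic genome-pair generator with planted orthologs (point-mutated
ancestral sequences, shared LCB membership, unrelated background genes)
makes the whole pipeline testable without external data.

## Worked example

```r
library(orthopair)

fx <- generate_genome_pair(sim_params(n = 50, m = 50, n_orth = 5,
                                      sub_rate = 0.1, seed = 1))
ds <- build_decision_system(fx$genome1, fx$genome2, fx$lcb, fx$labels,
                            feature_params(alignment_preset("blosum50")))
ds
#> <decision_system: 2500 pairs x 6 features; 5 orthologs>
class_stats(ds)
#> #Class (maj; min): (2495; 5)  %Class: (99.800; 0.200)  IR: 499.000

sp <- train_test_split(ds, fraction = 0.75, seed = 1)
ex <- run_experiment(sp$train, sp$test, algo = "svm", ros_percent = 100,
                     svm = svm_params(reg_param = 0.5), seed = 1)
ex$metrics
#> TP 1  FN 0  FP 0  TN 624
#> TPrate 1.0000  TNrate 1.0000  G-Mean 1.0000  AUC 1.0000
```

The 2500-pair universe holds 5 planted orthologs (IR 499); the single
ortholog that landed in the 25% test partition is recovered with no
false positives, so sensitivity, specificity and therefore G-Mean and
AUC are all 1. The feature separation driving this is large — per-class
feature means on the same fixture:

```r
round(colMeans(ds$features[ds$d == 1, ]), 3)
#>    S1    S2    S3 S4_w3 S4_w5 S4_w7
#> 0.754 1.000 1.000 0.773 0.764 0.760
round(colMeans(ds$features[ds$d == 0, ]), 3)
#>    S1    S2    S3 S4_w3 S4_w5 S4_w7
#> 0.016 0.797 0.335 0.160 0.173 0.169
```

A thin command-line wrapper covering the same pipeline (simulate →
features → stats/split → run) ships in `inst/cli/orthopair.R`:

```sh
Rscript inst/cli/orthopair.R simulate --outdir fixtures --n 50 --m 50 --orth 5 --seed 7
Rscript inst/cli/orthopair.R features --fasta1 fixtures/genome1.fasta \
    --fasta2 fixtures/genome2.fasta --lcb fixtures/lcb.tsv \
    --labels fixtures/labels.tsv --preset blosum50 --out features.tsv
Rscript inst/cli/orthopair.R split features.tsv --train train.tsv --test test.tsv
Rscript inst/cli/orthopair.R run --train train.tsv --test test.tsv \
    --algo svm --ros 100 --reg 0.5 --report report.json
```

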