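Package: orthopair
Title: Supervised Pairwise Ortholog Detection with Imbalance-Aware Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects orthologous gene pairs between two related genomes by
    supervised classification of every cross-genome protein pair. Six
    similarity features are computed per pair: averaged local/global
    alignment scores with affine gaps (Smith-Waterman, Needleman-Wunsch),
    normalized sequence-length difference, shared membership to locally
    collinear blocks (synteny), and the correlation of contact-energy
    moving-average spectra over gapless aligned regions at three window
    sizes. Because true orthologs are a tiny fraction of all pairs, the
    learners (linear hinge-loss SVM, random forest) are combined with
    random oversampling or cost-sensitive instance weighting, and models
    are scored with imbalance-aware metrics (G-Mean and a rate-based AUC).
    Includes a synthetic genome-pair generator with planted orthologs so
    the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
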