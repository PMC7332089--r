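Package: hydroxybench
Title: Homology-Aware Benchmarking of Proline Hydroxylation Site Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building homology-aware benchmarks of post-translational
    modification site predictors, using proline hydroxylation as the model
    system. Candidate sites are represented as fixed-length gapped sequence
    windows, scored pairwise with BLOSUM62 plus affine gap-run penalties,
    and clustered with UPGMA so that negatives resembling known positives can
    be removed before evaluation. Predictors are assessed site-centrically on
    balanced replica subsamples (sensitivity, specificity, balanced accuracy,
    F1, precision, Matthews correlation), with random and majority-vote
    consensus baselines, a cluster-seeded positional-profile scanner with
    E-value calibration as an upper-bound baseline, dataset characterization
    statistics, and a synthetic proteome generator emulating collagen-like
    (Gly-X-Y)n repeat proteins and sparse motif-borne signalling sites with
    configurable annotation incompleteness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
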