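Package: ocmetab
Title: Serum Metabolomics Biomarker Panel Discovery by Nested-LOOCV SVM-RFE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted LC-MS serum metabolomics biomarker discovery:
    simulation of run-level peak-area tables with pooled quality-control
    injections, blanks, batch structure and planted discriminative features;
    peak-list curation (presence filtering, total-area normalization,
    QC-drift purging, blank-baseline purging, duplicate averaging); linear
    support-vector-machine classification with a metabolic-score decision
    function and nested leave-one-out cross-validated recursive feature
    elimination for minimal diagnostic panel selection; orthogonal partial
    least squares discriminant analysis with several cross-validation schemes
    and label-permutation testing; per-feature univariate summaries (signed
    fold change, Mann-Whitney U) and PCA-based batch-bias inspection; and
    monoisotopic-mass/adduct arithmetic for negative-mode ion annotation with
    ppm mass errors and elemental-composition candidate search.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
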