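Package: stepsite
Title: Stepwise Combination of Evidence for Genomic Site Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition of translation initiation sites and stop codons by
    combining many heterogeneous base classifiers trained on different source
    genomes. Provides five base scorer families (position weight matrix,
    gain-ratio decision tree, Hamming k-nearest neighbours, weighted-degree
    string-kernel support vector machine and the in-frame stop-codon method),
    affine output scaling to [-1,1] with cross-validated decision thresholds,
    sum/majority/maximum combination rules, and greedy constructive and
    destructive stepwise ensemble selection optimising G-mean, auROC or auPRC
    on an imbalanced validation set. Includes imbalance-aware evaluation
    metrics, a Wilcoxon signed-rank comparison, a synthetic multi-species
    genome generator with planted sites for end-to-end studies, and an
    experiment driver with tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    kernlab,
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
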