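Package: bitterpep
Title: Sequence-Based Classification of Bitter Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes short peptide sequences into ten formula-defined
    descriptor families (amino acid composition, traditional and
    amphiphilic pseudo-amino-acid composition, adaptive skip dipeptide
    composition, dipeptide composition, dipeptide deviation from expected
    mean, grouped compositions, sequence-order-coupling numbers and
    quasi-sequence-order descriptors), fuses them into a single
    1,337-dimensional feature vector with zero-column removal, and trains
    and evaluates random-forest and comparison classifiers under
    stratified 10-fold cross-validation and independent-set testing. A
    seeded synthetic-peptide generator with a controllable hydrophobic
    composition shift makes the full pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    e1071,
    xgboost,
    rpart,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
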