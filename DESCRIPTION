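Package: methylMT
Title: Multi-Task Bidirectional GRU Prediction of DNA 4mC and 6mA Modification Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies DNA N4-methylcytosine (4mC) and N6-methyladenine (6mA)
    modification sites across multiple species with a multi-task recurrent
    neural network: overlapping n-gram tokenization of short sequence windows,
    a shared bidirectional gated recurrent unit (GRU) encoder with max-pooling
    over time, and per-species fully connected output heads trained jointly
    under a weighted binary cross-entropy objective. Includes labeled FASTA/TSV
    dataset handling, a synthetic motif-benchmark generator for controlled
    multi-task versus single-task ablation experiments, classifier evaluation
    (sensitivity, specificity, accuracy, Matthews correlation, AUC), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
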