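Package: codonMinMax
Title: Codon Usage Cluster Profiling and Host-Target Comparison for
    Heterologous Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes %MinMax sliding-window rare-codon cluster profiles of
    coding sequences under arbitrary codon usage tables, and two parameters
    that compare a gene's codon-cluster landscape between an expression host
    and the native organism: the mean absolute profile difference (delta
    %MinMax) and the window-wise Pearson correlation of the two profiles
    (%MinMax Correlation). Also provides the codon adaptation index (CAI),
    secondary-structure-stratified profile correlation, densitometric
    solubility quantification, binary classifier evaluation (prediction
    accuracy, Matthews correlation coefficient), regression-band outlier
    filtering, and a synthetic-data generator that emulates a heterologous
    expression screen with planted effects, so every analysis stage can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'errors.R'
    'genetic-code.R'
    'usage-table.R'
    'minmax-profile.R'
    'study-stats.R'
    'comparative-metrics.R'
    'structure-stratification.R'
    'synthetic-data.R'
    'io.R'
    'batch.R'
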