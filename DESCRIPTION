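Package: permdeg
Title: Permutation-Null Differential Expression for Small Two-Group
    RNA-Seq Designs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression analysis for two-condition bulk
    RNA-seq experiments with few biological replicates. Implements
    trimmed-mean-of-M-values (TMM) library normalization, a pseudocount
    log2 transform, gene-wise Student t-statistics referenced to a fully
    enumerated permutation null pooled across genes, Storey q-values,
    fold-change based DEG calling, Fisher/EASE gene-set
    over-representation, network table export, and delta-delta-Ct
    relative quantification for qPCR validation. A negative-binomial
    count simulator with planted effects, library-size variation and
    composition bias provides ground truth for calibration and power
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
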