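Package: poolscreen
Title: Pooled Deletion-Library Screens of Acquired Stress Resistance
Version: 0.9.0
Authors@R:
    person("Pool", "Screen", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of pooled yeast deletion-library selection screens for
    acquired (cross-)stress resistance: a population simulator for
    selection/outgrowth experiments with planted fitness defects, barcode
    (Bar-seq) read counting with mismatch-tolerant demultiplexing and tag
    mapping, TAG4-style barcode-array feature summarisation with quantile
    normalisation and saturation correction, per-strain log2 fitness scores
    across the sample-comparison design, multi-criterion calling of strains
    defective in acquiring hydrogen-peroxide tolerance, hypergeometric
    gene-set enrichment, interaction-network permutation tests, and scoring
    of survival-curve and GFP-competition validation assays.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
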