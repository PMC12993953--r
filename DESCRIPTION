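Package: histoclock
Title: Histone-Modification Epigenetic Clocks from ChIP-seq Peak Signal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds tissue- and mark-specific biological-age clocks from
    replicated histone-modification ChIP-seq peak calls and per-peak read
    counts. Covers consensus peak-set construction from replicate peak
    calls, reads-in-peaks density normalization with log2 transformation
    and background subtraction, empirical-Bayes batch correction that
    preserves age and sex covariates, per-peak Spearman age-association
    screening with Benjamini-Hochberg control and joint effect-size
    filtering, elastic-net age prediction under age-stratified
    leave-one-group-out cross-validation, noise-robustness and sample-size
    saturation protocols, quantile-rank benchmarking, super-enhancer
    stitching and fragmentation statistics, LOESS age-trajectory inflection
    detection, and a synthetic-data generator with ground truth for
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    glmnet,
    jsonlite,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
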