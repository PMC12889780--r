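Package: azfcCaller
Title: Calling Y-Chromosome AZFc gr/gr Deletions from Binned WGS Read Depth
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects gr/gr deletions and other copy-number variants of the
    ampliconic AZFc region of the human Y chromosome from whole-genome
    sequencing read depth. Depth is quantified across fixed-size bins tiling
    amplicon-class intervals, normalized against a single-copy control region,
    median-centered across a cohort to remove marker-specific multiplicative
    biases, rounded to integer copy numbers and matched against a catalog of
    architecture signatures. Includes a truth-labeled synthetic depth
    simulator with binomial read thinning for coverage titration, confusion
    matrix based benchmarking, Firth's bias-reduced logistic regression for
    rare-carrier case-control association, and fixed-effect and
    DerSimonian-Laird random-effects inverse-variance meta-analysis with
    heterogeneity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
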