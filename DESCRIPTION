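Package: meltsex
Title: Sex Determination from Duplex RT-qPCR Melt Curves by High-Resolution Melt Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for RNA-based mammalian sex determination from duplex
    RT-qPCR melt curves. A duplex assay co-amplifies a housekeeping control
    transcript (ACTB) and the X-inactivation transcript XIST, which is
    expressed only in individuals with two or more X chromosomes; the two
    amplicons melt at distinct temperatures, so the presence or absence of
    the lower melt transition separates females from males. The package
    provides a synthetic duplex melt-curve simulator with ground-truth
    labels, long-format plate I/O, high-resolution melt (HRM) processing
    (derivative melt peaks, two-line pre/post-melt normalization, difference
    curves against an automatically selected reference), shape- and
    Tm-constrained agglomerative clustering of wells, anchor-based cluster
    sex mapping with a majority-rule (>= 2/3 of replicate wells) per-sample
    caller, concordance reporting against DNA-based truth labels, and a
    small exact-match in-silico PCR utility with empirical amplicon Tm
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
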