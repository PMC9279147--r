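Package: loopferret
Title: Dissection of Clustered-CTCF Domain Boundaries in Chromatin Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect topologically associating domain (TAD) boundaries
    built from clusters of oriented CTCF binding sites (CBSs). Provides a 1D
    cohesin loop-extrusion simulator with orientation-dependent CTCF stalling
    and a steric loop-interference rule that renders Hi-C-like contact maps
    with ground-truth annotations; contact-matrix I/O, Sinkhorn-Knopp (KR-type)
    balancing, expected-by-distance and observed/expected transforms; insulation
    scores, boundary calls and boundary scores with mixture-model mappability
    masking; PWM-based CBS orientation assignment and boundary composition
    statistics; loop-anchor and loop-pair classification (convergent,
    nonconvergent and associated categories), bidirectionality statistics,
    loop strength and aggregate loop signal; per-diagonal z-score subtraction
    maps and virtual 4C profiles; and end-to-end synthetic experiments that
    recover boundary-composition and loop-interference signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    mclust,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
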