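Package: loopRewire
Title: Differential Chromatin Loop, Compartment and Occupancy Analysis on
    Contact Maps and Fragment Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for detecting chromatin-loop rewiring and
    compartment changes between two conditions from cis Hi-C contact maps,
    together with background-normalized differential occupancy analysis of
    CUT&RUN/ATAC-style fragment coverage and the integration statistics that
    connect the two: observed-over-expected normalization, masked-kernel
    smoothing, Hiccup-style donut loop scoring and calling, per-sample
    z-normalized scores combined across replicate pairs by Stouffer
    meta-analysis, A/B compartment eigenvector and saddle-plot analysis,
    median-of-ratios background size factors with subsampling, a simplified
    Wald test for differential regions, peak-to-gene scoring, hypergeometric
    overlap tests, and anchor-level gain/loss bias statistics. A synthetic
    data generator with planted ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
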