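Package: poretag
Title: Event Detection and Probe Design for Osmium-Tagged Nanopore
    Silencing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-molecule ion-channel experiments on Oxford
    Nanopore flow cells repurposed as counting sensors for osmylated
    oligonucleotide probes. Implements threshold-based segmentation of raw
    per-channel current traces (median baseline, segmented noise
    estimation, dwell-time and residual-current filtering), residual
    current ratio histograms, outlier-channel flagging, and the
    probe-silencing presence/absence and quantification rules. A companion
    design module derives osmylated complementary probes from a target
    sequence and computes chromophore ratios, pseudo-first-order
    osmylation kinetics, ungapped duplex scores, hybridization feasibility
    and recommended applied voltage. A seeded simulator generates
    multi-channel traces with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'detection.R'
    'reporting.R'
    'decision.R'
    'sequences.R'
    'probe-design.R'
    'simulate.R'
    'trace-io.R'
    'poretag-package.R'
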