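Package: cumcnv
Title: Cumulative Copy Number Variation Profiles from DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives cumulative copy-number-variation (CNV) profiles from
    methylation-array log2-ratio data. Provides control-based normalisation of
    probe intensities (linear reference fit and tangent projection), genomic
    binning with iterative window merging, two segmentation modes (a
    multi-sample penalised least-squares piecewise-constant fit with shared
    breakpoints, and per-sample circular binary segmentation with optional
    inverse-variance bin weights), noise-adjusted aberration calling,
    chromosome-arm condensation with similarity ordering, cumulative intensity
    and frequency plot data, and a Monte Carlo benchmark for focal-aberration
    sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
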