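Package: octascan
Title: Octamer-Based Prediction of Cis-Regulatory Elements in Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts cis-regulatory elements in fixed-length promoter
    regions from expression-responsive gene sets using an octamer (8-mer)
    enrichment statistic, the Relative Appearance Ratio (RAR). Octamer
    occurrences in a responsive promoter set are compared against a total
    genic promoter set; one-sided Fisher exact tests convert each ratio
    into a LOD score used to mask statistically unsupported octamers
    (RARf). Promoters are then scanned base-by-base with the masked table
    and above-threshold windows are merged into predicted elements, which
    are annotated with transcription-factor recognition motifs and a
    catalog of position-dependent regulatory element group (REG) octamers.
    Includes co-localization contingency analysis, detection of regulatory
    crosstalk between treatment tables, a synthetic promoter generator
    with planted motifs for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
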