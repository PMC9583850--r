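Package: gatescore
Title: Characterization of Yeast CRISPR-dCas9 Logic-Gate Circuits from
    High-Throughput Flow-Cytometry Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for assessing the digital
    correctness of two-input logic gates engineered into Saccharomyces
    cerevisiae and read out by green fluorescent protein (GFP)
    fluorescence. Provides scatter gating and per-well aggregation of
    flow-cytometry events, calibration of a single high/low GFP threshold
    from positive (NOR00) and negative (wild-type) control wells by
    minimizing the mean wrong-direction distance, replicate/strain/circuit
    truth-table correctness scoring, k-means diagnostics for bimodal
    scatter structure, plate-reader dilution and growth checks, and
    verification of strain builds by exact guide-RNA matching against
    sequencing reads. A synthetic-data generator emulates the statistical
    structure of such campaigns (log-normal scatter mixtures with debris
    and instrument saturation, well-level output-mode failures, plate
    layouts, reads with injectable design anomalies) so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
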