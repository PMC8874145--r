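Package: abcflow
Title: Quantitative Surface-Antigen Expression Profiling on Blood Leukocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardized workflow for quantitative surface-antigen
    expression profiling on blood leukocytes by flow cytometry: FCS 3.0
    reading and writing, plate-layout driven file annotation and protocol
    generation, spillover compensation, hierarchical template gating of 27
    leukocyte subsets across an innate and an adaptive tube, calibration of
    PE fluorescence to antibody binding capacity (ABC) units with four-peak
    quantitation beads, fluorescence-minus-one background cutoffs, antibody
    titration analytics with Stain Index based titer selection, clone
    benchmarking, and cross-site reproducibility summaries. Includes a
    synthetic event-data generator so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
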