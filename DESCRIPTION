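Package: droughtring
Title: Tree-Ring Chronologies, Climate Response and Drought Resilience Indices
Version: 0.1.0
Authors@R: person("Dendro", "Lab", email = "dendro@example.org", role = c("aut", "cre"))
Description: Builds standardized tree-ring chronologies from Tucson-format
    ring-width collections using a frequency-cutoff cubic smoothing spline,
    computes chronology quality statistics (mean sensitivity, interseries
    correlation, expressed population signal), correlates chronologies with
    monthly climate over a dendrochronological window with bootstrap
    confidence intervals, and quantifies per-tree drought resistance,
    recovery, resilience and decline-rate indices over a historical drought
    calendar. Includes a synthetic forest generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
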