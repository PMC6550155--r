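Package: graphokin
Title: Kinematic Handwriting Analysis and Dysgraphia Screening from Digitizer Pen Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of online handwriting recorded on a
    digitizer tablet. Reads time-stamped pen traces (position, pressure, tilt,
    on-surface state), extracts a bank of static, kinematic, pressure and tilt
    features -- including packetized power-spectral summaries and a
    cross-product tremor signal -- and screens writers for dysgraphia with a
    Random Forest under a repeated stratified split protocol with Gini
    importance ranking and duration-robustness curves. A seeded synthetic
    handwriting simulator with controllable group structure supports testing
    and power experiments without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
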