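Package: erfusion
Title: Evidential Reasoning for Multi-Source Evidence Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines bodies of evidence expressed as belief distributions
    over a common frame of discernment. Implements the weighted recursive
    evidential reasoning (ER) combination with explicit separation of
    incompleteness-driven and weight-driven ignorance, together with the
    classical Dempster, Yager and Murphy combination rules. Supports flat
    evidence tables read from CSV or XLSX files, hierarchical bottom-up
    fusion over a tree-structured directory of assessment attributes, a
    command-line interface, bar-chart visualisation of fused results, and
    a deterministic random-evidence generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    optparse,
    readxl,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
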