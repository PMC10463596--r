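Package: majs
Title: Majority-Sign Consistency Modelling of Signed Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confronts a signed directed interaction graph (activation and
    inhibition edges) with discrete change-of-state observations (+, 0, -)
    under a majority-sign semantics: every node's sign must follow the
    majority of its received influences and carries an integer confidence
    weight in [0, 100]. Inconsistencies between network topology and data are
    repaired by adding a minimal number of artificial influences under a
    per-node budget K; all optimal answer sets are enumerated and projected
    into per-node weighted predictions for unobserved species. Discrete
    weighted predictions can be scored against continuous fold changes
    through a three-component normal mixture and a normalised significance
    score. Includes readers for edge-list and SIF graphs, observation lists,
    expression-table discretisation, and deterministic synthetic instance
    generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
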