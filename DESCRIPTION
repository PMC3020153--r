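Package: copdAD
Title: Decision-Analytic Modelling of Advance Directive Choices in COPD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A decision-analytic model that recommends a chronic obstructive
    pulmonary disease (COPD) advance directive -- Full Code (invasive
    mechanical ventilation allowed) versus Do Not Intubate (DNI) -- by
    maximizing expected quality-adjusted life years (QALYs) over a decision
    tree of an index exacerbation hospitalization.  Includes a generic
    decision-tree engine with expected-value rollback and exhaustive path
    enumeration, DerSimonian-Laird random-effects pooling with the model's
    homogeneity decision rules, the declining exponential approximation of
    life expectancy (DEALE), linear time-tradeoff utility construction
    (allowing states worse than death), and one-way, two-way and threshold
    sensitivity analyses with tornado and preference-grid outputs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
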