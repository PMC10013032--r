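Package: fopnet
Title: Reduced Generalized Net Engine for Foreign-Object-Principle Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event engine for reduced Generalized Nets, a Petri-net
    extension in which transition conditions are predicate-valued index
    matrices, tokens carry timestamped characteristic histories, and all
    events refer to a global tick clock. Ships a parameterized builder for a
    Foreign-Object-Principle net that models how a system (for example a
    human body) receives impacts from its environment through thresholded
    receptors, processes them in internal components, and emits reactions
    through effectors, with feedback-controlled receptor thresholds. Includes
    a lightweight thresholded impact-reaction reference model, executable
    physiological scenarios (acute pain reflex, chronic pain with threshold
    adaptation, intake/excretion exchange), a seeded stimulus generator,
    YAML scenario configs with schema validation, auditable line-delimited
    traces, and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
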