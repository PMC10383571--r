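Package: shapcf
Title: Shapley and Counterfactual Explanations for Multiclass Compound
    Activity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains multiclass random-forest models that distinguish
    dual-target, single-target and random compounds from binary
    atom-environment fingerprints, computes exact interventional Shapley
    attributions for every fingerprint bit by traversing the exported
    trees, aggregates present- and absent-feature contributions per class,
    searches narrow chemical space for counterfactual analogues that flip
    single-target predictions to dual-target, and projects attributions
    back onto atoms for color-coded structure depictions. A synthetic
    benchmark generator with planted structural motifs makes the whole
    workflow reproducible without external compound databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    ranger,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
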