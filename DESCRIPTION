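Package: perisharm
Title: Rule-Based Detection of Perinatal Self-Harm Mentions in Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A rule-based clinical natural language processing pipeline that
    detects mentions of acts of self-harm in free-text psychiatric clinical
    notes, resolves each mention's status (relevant, non-relevant, uncertain),
    temporality (current, historical) and polarity (positive, negative),
    aggregates mentions to service-user level with a configurable
    two-or-more-mentions flagging heuristic, and evaluates output against a
    gold standard with span matching, micro- and macro-averaged precision,
    recall and F-score, Cohen's kappa, diagnostic likelihood ratios with
    confidence intervals, and post-test probabilities.  Includes a synthetic
    pseudo-EHR generator with gold annotations so every pipeline stage is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    stringi,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
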