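Package: grasp
Title: Evidence-Based Grading and Assessment of Clinical Predictive Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades clinical predictive tools (prediction rules, risk scores,
    predictive algorithms) from structured registries of their published
    evaluation evidence. Each tool receives a grade code combining the highest
    phase of evaluation reached (predictive performance before implementation,
    usability and potential effect during implementation, post-implementation
    impact), the level of evidence within that phase, and the direction of the
    evidence, with a deterministic protocol for resolving mixed (discordant)
    study conclusions by study quality, specification match, sample size and
    recency. Includes registry input/output in JSON, YAML and CSV with schema
    validation, detailed per-tool appraisal reports and registry-wide summary
    tables, packaged evidence corpora for five widely used predictive tools
    (LACE Index, Centor Score, Wells' Criteria, MEWS, Ottawa Knee Rule), a
    seeded synthetic-corpus generator with planted ground-truth grades for
    property testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
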