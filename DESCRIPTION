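Package: faithboost
Title: Skill Acquisition and Teammate Loyalty in Online Team Games
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how grouping behaviour shapes skill
    acquisition in online competitive games. Implements Bayesian skill
    rating over chronological game histories (Gaussian skill beliefs with
    moment-matched two-team updates in the TrueSkill family, plus an Elo
    baseline), grouping-behaviour metrics (team-oriented behaviour,
    teammate loyalty and their product, faithfulness), learning-curve
    aggregation with Hodges-Lehmann pseudomedians and law-of-practice
    power-law fits, cross-sectional and mixed-effects models of behaviour
    effects on skill, and an agent-based generator of synthetic game
    histories for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    stats,
    tibble,
    utils,
    withr
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
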