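Package: spyquest
Title: Simulation and Scoring Engine for Suspect-Elimination Question Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, seedable research engine for 20-questions-style
    hidden-object games in which a player identifies a hidden "spy" among a
    room of visually distinct suspects by asking yes/no questions. Provides
    room generation over finite attribute schemas, a truthful answer oracle
    with a three-way chatbot response contract, keyword pattern-matching
    classification of free-text questions into (property, value) labels,
    harmonic-weighted question-effectiveness scoring (QEM and its
    ground-truth "effective" variant), simulated player policies
    (constraint-seeking, hypothesis-scanning, random, noisy-human),
    JSON-lines transcript I/O with session summary tables, and a win/loss
    outcome-analysis stage combining SMOTE class rebalancing with logistic
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
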