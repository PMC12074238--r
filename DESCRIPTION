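Package: pamsim
Title: Simulation and Ordinal Analysis of Performance Accommodation
    Mechanisms in Serious Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-driven simulator of a blink-controlled fishing
    rehabilitation game with scheduled input imprecision (simulated
    brain-computer-interface false negatives) and three explicit help
    mechanisms (augmented success, mitigated failure, input override).
    Computes per-session game measures (blink recognition and conversion,
    positive feedback, help rate, fish caught/lost/reeled/unreeled),
    generates synthetic seven-point Likert ratings from a cumulative-logit
    model with participant random intercepts, and fits and compares
    cumulative link mixed models via the Laplace approximation, with
    likelihood-ratio tests, AIC ranking, ICC(3,k), Spearman correlation
    and Bartlett's test of sphericity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma
Config/testthat/edition: 3
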