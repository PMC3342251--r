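Package: pairlead
Title: Continuous-Time Markov Models of Leadership in Foraging Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of leadership and followership in pairs of animals
    alternating between a refuge and an exposed foraging area, modelled as
    a 12-state continuous-time Markov chain whose states track each
    individual's location, the identity of the fish that initiated the
    current trip, and whether its partner has joined.  Provides exact
    transition-time maximum-likelihood estimation under parameter-tying
    schemes (full, initiator-only, memory-free), log-linear temperament
    covariates, likelihood-ratio and AIC model comparison, pair-resampling
    bootstrap inference, initiation-sequence statistics (runs and sign
    tests), and a Gillespie-style generator of synthetic behavioural event
    logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
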