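Package: ndra
Title: Naive Discriminative Reading Aloud
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-route discriminative-learning simulator of the reading
    aloud task. Orthographic input (letters and letter bigrams) activates
    lexical representations through a Rescorla-Wagner association network
    solved at equilibrium, and lexemes in turn activate demi-syllable
    phonological units. Per-item activation profiles (visual complexity,
    lexeme activation, demi-syllable activations and their Shannon entropy)
    are integrated multiplicatively into simulated naming latencies for both
    words and non-words, and a top-down checking mechanism assembles actual
    pronunciations in DISC notation. Includes a synthetic-lexicon generator
    with Zipfian token frequencies and controllable spelling-to-sound
    consistency, plus evaluation helpers (latency transforms, scaled-predictor
    effect sizes, principal-components regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
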