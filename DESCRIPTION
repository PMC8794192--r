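Package: iterlang
Title: Iterated-Learning Transmission Chains for Artificial Mini-Languages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates iterated-learning transmission chains over a small
    artificial language (a 2 agents x 2 numbers x 4 events meaning space with
    redundant agent-marking on verbs) and measures how morphological
    overspecification erodes under imperfect learning. Provides a generator of
    structurally isomorphic generation-0 languages, a parameterised imperfect
    learner, type-token-ratio complexity metrics at the whole-language,
    part-of-speech and morpheme level, Levenshtein-based transmission fidelity,
    Shannon entropy, Welch t-test contrasts, and condition-by-generation
    mixed-effects trend models with a per-chain slope fallback. Chain logs are
    read and written as TSV, run configurations as JSON.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
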