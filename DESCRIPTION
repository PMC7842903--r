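Package: predread
Title: Cloze and Corpus-Based Word Predictability for Reading Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating lexical and morphosyntactic word
    predictability from human cloze responses and from corpus-trained
    language models, and for quantifying how each probability source
    contributes to eye-fixation durations during sentence reading.
    Includes an interpolated Kneser-Ney n-gram language model with ARPA
    import/export and a pluggable distribution-provider interface,
    cumulative-cloze aggregation with zero smoothing and logit transforms,
    word-class and morphological-feature probability derivation over
    ambiguous analyses, extraction of standard fixation-duration measures
    (single fixation duration, first fixation duration, gaze duration,
    total reading time), hierarchical lognormal duration models with
    k-fold goodness-of-fit comparison and residual-complementarity
    analysis, and a seeded synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
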