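Package: cogspeech
Title: Speech-Derived Digital Biomarkers of Cognitive Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline linking spontaneous speech to
    cognitive performance in older adults. Extracts lexical, syntactic,
    semantic and acoustic features from picture-description transcripts and
    recordings (lexical diversity indices, part-of-speech ratios, pause and
    rate statistics, a subset of eGeMAPS-style descriptors), derives four
    standardized cognitive domain composites (language, executive function,
    memory, speed) by confirmatory factor analysis, and evaluates support
    vector regression models of those composites under a leakage-safe
    stratified split and cross-validation design with bootstrap inference and
    Shapley attributions. Includes normative z-score screening for cognitive
    low performers with ROC/PR analysis, frozen-model transfer to an external
    clinical cohort, and a fully synthetic cohort generator so the entire
    analysis is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
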