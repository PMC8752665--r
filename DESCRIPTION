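Package: tempemo
Title: Weakly Supervised Temporal Orientation and Emotion Analysis of Microblog Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-layer generative-discriminative pipeline for measuring
    tweet-level temporal orientation (past/present/future) together with emotion
    class (joy/sadness/anger/fear) and emotion intensity. Weak labelling
    functions (temporal lexicons, keyword lists, part-of-speech rules, and
    trainable weak classifiers) are fused by a factor-graph generative label
    model fit by exact marginal-likelihood minimisation, including estimation of
    pairwise correlation structure among the labelling functions. The resulting
    probabilistic labels train a hard-parameter-sharing multi-task network
    (shared embedding, Bi-GRU and CNN branches, shared MLP, task heads for
    temporal class, emotion class and intensity regression). Tweet-level
    predictions aggregate to user-level orientation and emotion fractions whose
    associations are quantified by Pearson correlation. A synthetic-corpus
    module with planted structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
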