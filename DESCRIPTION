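Package: dtipair
Title: Drug-Target Interaction Prediction in a Within/Between-Score Pair Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts drug-target interactions from a bipartite interaction
    network plus chemical and sequence similarity matrices. Computes
    matching-index topological similarity, combines it with the input
    similarity by a degree-adaptive rule, represents every drug-target pair
    as a four-dimensional vector of within-scores and between-scores,
    embeds all pairs by principal component analysis, and uses the distance
    to the origin of that pair space as the interaction confidence score.
    Includes leave-one-out cross-validation (AUC/AUPR), top-k candidate
    ranking, a synthetic block-structured network generator, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
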