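Package: emagent
Title: Episodic Memory Gating in a Recurrent Event-Prediction Agent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates neocortical-hippocampal interaction during event
    understanding. A recurrent (LSTM) network with a trainable episodic
    memory gate stores snapshots of its cell state and retrieves them
    through a competitive leaky-competing-accumulator process; the whole
    agent is meta-trained with supervised pre-training followed by an
    advantage actor-critic objective on a synthetic event-prediction task
    with recent-memory, distant-memory and no-memory conditions. Includes
    evaluation analyses (condition time courses, retrieval-gate traces,
    recall timing under penalty, schema-strength sweeps, encoding-policy
    comparisons, working-memory state similarity) and multivariate
    decoding of the working-memory state.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
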