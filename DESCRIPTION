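Package: teamnet
Title: Team Performance Analysis from Collaboration Networks and Score Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying small-team performance on sequential task
    batteries. Extracts directed, time-decay weighted collaboration networks
    from timestamped chat logs via response-window detection, computes
    network-topological, spectral, chat-log and score-dynamics feature sets,
    fits sparsity-filtered elastic-net models of per-task team performance,
    provides standard score-series forecasting baselines, and simulates
    online workload-distribution policies that trade off exploiting
    high-performing teams against a quadratic fairness penalty on the
    probability simplex. A synthetic-data generator emulates score tables,
    reply-process chat logs with a planted member-affinity structure,
    baseline team features and response annotations, so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
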