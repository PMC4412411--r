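Package: oneshot
Title: One-Shot Causal Learning Models for Trial-Based Rating Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the transition between incremental and
    one-shot causal learning in trial-based stimulus-outcome tasks. Implements
    a Dirichlet causal-inference learner whose learning rate is allocated by a
    softmax over per-stimulus causal uncertainty (posterior variance), together
    with a zoo of competitor models (Rescorla-Wagner, Pearce-Hall,
    probabilistic contrast, Bayesian causal structure learning, heuristic and
    random raters). Provides a synthetic task and rating generator emulating
    rounds of five trials with 16:8:1 stimulus presentation frequencies and a
    single novel outcome, multi-start Nelder-Mead fitting of model parameters
    to causal ratings with leave-one-out cross-validation model comparison, and
    the event-level analyses that characterise one-shot learning: 90th
    percentile learning-rate classification, one-shot effect indices, Gaussian
    mixture threshold validation, Granger-causality checks on uncertainty
    reduction, and principal-component regularity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mclust,
    lmtest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
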