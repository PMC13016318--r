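Package: concretecascade
Title: Intracranial Broadband-Gamma Analysis of Concreteness Judgements
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: A reusable, tested pipeline for intracranial EEG studies of
    single-word concreteness judgements: broadband gamma (70-150 Hz)
    envelope extraction from continuous multichannel recordings,
    baseline-normalized epoching with a responsiveness filter,
    timepoint-wise hierarchical mixed-effects contrasts with FDR control,
    surface-based mixed-effects mapping with smoothness-matched Monte
    Carlo cluster family-wise error correction, sliding-window
    single-trial decoding with permutation nulls and a support-vector
    regression model comparison for midscale words, directed network
    inference via partial directed coherence from multivariate
    autoregressive models, and behavioral / stimulation statistics
    (diagnostic odds ratio, binomial GLMM). A synthetic-cohort generator
    with planted ground truth stands in for patient recordings so every
    stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    e1071,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
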