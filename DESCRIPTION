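Package: temponet
Title: Time-Varying Sparse Causal Network Inference from Time-Course
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers simple time-varying causal networks from short
    time-course transcriptome experiments. Transcripts passing a
    fold-change filter are grouped into temporal templates by resampled
    consensus clustering with a correlation-distance k-means, and the
    templates at consecutive time points are linked by sparse transition
    matrices estimated with a sliding-window weighted least-squares loss,
    an L1 sparsity penalty, and a temporal-smoothness penalty, optimized
    by block coordinate descent with proximal-gradient block updates.
    Regularization strengths are selected by BIC over a grid. Includes a
    synthetic-data generator for sparse time-varying linear dynamics and
    support-recovery scoring, plus a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
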