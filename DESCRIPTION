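Package: tempro
Title: Consensus Profiling of Time-Series Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for time-course expression studies with
    unbalanced group designs. Ranks genes by differential expression across
    time groups using three moderated ANOVA statistics (empirical-Bayes
    variance shrinkage, windowed variance regularization, and a
    permutation-calibrated multiclass d statistic), combines them into a
    conglomerate ranking with beta-uniform-mixture and permutation false
    discovery rates, groups the significant genes into robust time-profile
    clusters by K-means co-occurrence consensus clustering with Ward
    consensus cuts and optimal leaf ordering, tests per-cluster annotation
    term over-representation with overlap-based term grouping, and scores
    transcription-factor motif over- and under-representation in cluster
    promoter sets as binomial Z statistics against a pooled background.
    Includes a synthetic-data generator that plants time profiles, promoter
    motif sites and enriched annotation terms so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    Biostrings,
    fgsea,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
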