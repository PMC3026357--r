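Package: arrayConcord
Title: Concordance of Differentially Expressed Gene Lists from Two-Sample
    Microarray Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing cross-experiment agreement of microarray
    differential-expression results between two reference samples. Implements
    probe-level to gene-level summarization (RMA-style background correction,
    quantile normalization and median-polish summarization), MAS5-style
    scaling factors and Present/Absent detection calls for array quality
    reporting, Welch t statistics with fold-change-ranked selection of
    equal-size up/down gene lists, and the percentage-of-overlapping-genes
    (POG) concordance statistic with POG-versus-list-size curves, reference
    confidence bands and three directional-agreement scenarios. A synthetic
    probe-level data generator with known ground truth emulates paired
    reference/degraded platforms, including fold-change compression, reduced
    intensity and inflated background, so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
biocViews: Microarray, Preprocessing, DifferentialExpression,
    QualityControl, Software
RoxygenNote: 7.3.3
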