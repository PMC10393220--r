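Package: phipkit
Title: Proteome-Wide PhIP-Seq Autoantibody Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of phage immunoprecipitation sequencing (PhIP-Seq)
    autoantibody screens from peptide-level read counts through gene-level
    fold-change-over-mock-IP enrichment, leave-one-out z-score positivity
    calling, Kolmogorov-Smirnov group comparisons, L1-regularized logistic
    regression cohort classification, peptide-level epitope localization,
    and Gonnet PAM250 cross-reactivity scans against a viral proteome.
    Includes a seeded synthetic-cohort generator with planted antigen
    reactivities for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    glmnet,
    pROC,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
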