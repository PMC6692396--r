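Package: qpcrDRS
Title: Host-Transcript Disease Risk Score Pipeline for RT-qPCR Data
Version: 0.1.0
Authors@R:
    person("qpcrDRS", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for classifying viral versus bacterial
    infection in febrile children from RT-qPCR threshold-cycle (Ct) data of
    a two-gene host signature (IFI44L, FAM89A). Implements replicate-level
    quality control, four reference-gene stability algorithms (geNorm,
    NormFinder, BestKeeper, comparative delta-Ct) with a comprehensive
    geometric-mean-of-ranks ranking, delta-Ct and 2^-ddCt relative
    quantification, the two-transcript and one-transcript Disease Risk
    Score, ROC/AUC analysis with Youden cut-points and stratified bootstrap
    confidence intervals, group-comparison decision trees (Shapiro-Wilk,
    variance tests, ANOVA/Welch/Kruskal-Wallis, Tukey/Games-Howell), a
    two-sample t-test power calculator, and a synthetic cohort generator
    for end-to-end testing without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
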