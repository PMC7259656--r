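Package: idoRT
Title: Tumor-Immune Growth Modelling for Combined Radiotherapy and IDO1
    Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time tumor-immune dynamics for a rat glioblastoma model
    treated with fractionated radiotherapy and the IDO1 inhibitor
    1-methyl-tryptophan: Gompertz growth with linear-quadratic radiation kill,
    radiation-triggered immune effector recruitment, and drug-potentiated
    immune-mediated kill.  Includes least-squares calibration of the model to
    day-18 group mean tumor cross-section areas with bootstrap-with-replacement
    uncertainty, two-fraction interval scanning, the study-level inferential
    statistics (one-way ANOVA with Bonferroni post-hoc tests, Welch t,
    Kaplan-Meier medians and log-rank comparison), two-group log2 fold-change
    analysis of expression matrices, and a seeded synthetic-cohort generator
    emulating the experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
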