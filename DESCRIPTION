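Package: sensiscreen
Title: Scoring Arrayed siRNA Drug-Sensitization Screens and Knockdown
    Expression Consensus Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for arrayed RNA-interference drug-modifier screens and
    the follow-up expression profiling of gene knockdowns. Screen wells are
    normalized to the per-plate median of non-targeting (GL2) control wells,
    each gene is assigned a sensitization index (SI, the ratio of
    control-normalized viability under drug to that under vehicle), drug
    effects are tested with per-gene linear models (optionally with
    empirical-Bayes variance moderation) and Benjamini-Hochberg correction,
    and hits are called by a dual statistical (FDR) and biological (SI)
    criterion with deconvolution validation and multi-drug specificity
    matrices. A companion arm computes per-knockdown log2 fold changes
    against control samples, finds genes consistently regulated across all
    knockdowns, and tests cytogenetic-band and curated gene sets by Wilcoxon
    rank-sum statistics with Bonferroni correction. A synthetic-data module
    simulates plate screens and expression matrices with planted ground
    truth so every stage of the pipeline is verifiable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    limma,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
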