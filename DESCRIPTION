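Package: ebmex
Title: Empirical Bayes Integration of Gene Expression and Promoter Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical empirical Bayes modeling of probe-level gene
    expression and promoter DNA methylation measured in two conditions.
    Fits gene-level condition means, probe effects and error variances by
    an EM algorithm, computes exact Gaussian posteriors of per-gene
    expression and methylation changes, classifies genes into nine
    regulation categories (up/down/no-change expression crossed with
    hyper/hypo/no-change methylation) with posterior-probability false
    discovery rate control, and summarizes global and gene-specific
    expression-methylation correlations. Includes a generative simulator
    with known ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mvtnorm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
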