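Package: flankfda
Title: Functional Data Analysis of Genomic Landscapes Flanking Integration Sites
Version: 0.1.0
Authors@R: person("flankfda", "maintainers", email = "maintainers@flankfda.dev",
    role = c("aut", "cre"))
Description: Quantifies genomic feature tracks in fixed-width windows flanking
    transposable-element integration sites, screens features for
    multicollinearity by hierarchical clustering on Spearman correlations, and
    compares two groups of regions with an extended Interval Testing Procedure:
    synchronized two-sample permutation tests on every window, nonparametric
    combination over all contiguous window intervals, and family-wise error
    adjusted p-values at every maximum interval length. Features classified as
    invariant or localized differential landscape signals feed single and
    multiple functional logistic regression models with deviance-explained
    screening, LASSO subset selection of scalar predictors, stepwise addition
    of functional predictors, and per-predictor relative contribution to the
    deviance explained. Includes a synthetic-data generator with known
    differential structure for end-to-end validation, plus readers and writers
    for BED, bedGraph and curve-matrix TSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
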