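Package: shortform
Title: Short-Form Construction for Ordinal Scales via Item Response Theory
    and Optimal Test Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating short forms of polytomous
    questionnaires such as the Weinstein Noise Sensitivity Scale. Implements
    the generalized partial credit model (marginal maximum likelihood via EM,
    expected a posteriori scoring, item and test information), essential
    unidimensionality screening by minimum-residual factoring of the
    polychoric correlation matrix, gender differential item functioning
    detection with the iterative Wald approach (all-others-as-anchors screen,
    MaxA5 anchor selection, anchored Wald tests), exact item selection by
    branch-and-bound maximization of test information at anchor trait levels,
    and short-form evaluation (Cronbach's alpha with Feldt intervals, score
    correlations, one-factor confirmatory factor analysis fit indices, and
    information-retention summaries). A synthetic-data generator with known
    item parameters, planted differential item functioning, reversed items
    and correlated covariates supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
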