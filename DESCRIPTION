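Package: laxkat
Title: Linear Maximum Kernel Association Testing for High-Dimensional
    Brain-Behavior Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-component association testing for high-dimensional
    predictors (e.g., vertex-wise cortical thickness) with global and local
    (region-of-interest) inference. Implements the LaxKAT statistic, the
    maximum of the scaled SKAT quadratic form over a pre-specified subspace
    of linear kernels -- an atlas parcellation or an arbitrary diagonal
    basis -- with permutation inference for Gaussian and Bernoulli
    responses, analytic chi-square-mixture p-values for the Gaussian case,
    Holm-corrected local tests, a mass-univariate baseline, and a synthetic
    data simulation harness for power, familywise error and false discovery
    rate evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
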