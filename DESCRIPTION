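Package: kernelcor
Title: Kernelized Correlation for Nonlinear Dependence in Paired Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the kernelized correlation coefficient, a
    sign-preserving nonlinear dependence measure for paired series: the two
    series are viewed as T points in the plane, mapped through a polynomial
    or Gaussian (RBF) kernel Gram matrix, double-centered, and the resulting
    kernelized vectors are plugged into Pearson's correlation. Includes the
    plug-in t-test significance rule, across-replicate one-sample t-tests,
    cross-validation training of the RBF width from replicate agreement, a
    condition self-correlation screen, baseline measures (Pearson, Kendall
    tau-b, distance correlation), simulation generators for three nonlinear
    test cases with type-I error and power tables, expression-table input
    and output, and an all-pairs correlation engine with multiple-testing
    correction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
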