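Package: mccinfer
Title: Asymptotic Confidence Intervals for the Matthews Correlation Coefficient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimation and asymptotic interval inference for the
    Matthews correlation coefficient (MCC, the phi coefficient) of a binary
    classifier, based on the multinomial central limit theorem and the delta
    method. Implements three single-MCC interval methods (the direct
    delta-method "Simple" interval, Fisher's z transformation with a
    delta-method variance, and the naive normal-theory 1/(n-3) variance) and
    three interval methods for the difference of two MCCs evaluated on the
    same subjects (Simple, Zou's MOVER-style interval, and a modified
    artanh transformation of the difference). Includes a vectorized
    Monte-Carlo engine for coverage-probability studies under multinomial
    sampling, scenario constructors for balanced and imbalanced designs, and
    utilities to reconstruct the 2x2x2 joint distribution of two paired
    classifiers from marginal sensitivities and specificities with
    partial-identification bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
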