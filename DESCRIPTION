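Package: pattsig
Title: Visual-Signature Distinguishability of Animal Color Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether two classes of animal body
    color patterns are visually distinguishable. Images are white-standard
    calibrated, cropped to the body, and encoded as biologically inspired
    visual signatures: Gabor filter responses pooled into a shift-tolerant
    C1 representation over the luminance channel and eight rectified
    single-opponent color channels, then summarized as maximal similarities
    to a dictionary of randomly sampled templates (C2 features).
    Distinguishability of labeled pattern classes is quantified by the
    leave-one-out success rate of a linear support-vector classifier with a
    label-permutation significance test. Supporting field statistics
    (2x2 chi-square, exact binomial, maximum-likelihood logistic regression
    with likelihood-ratio tests, one-way ANOVA with Tukey HSD) and a
    synthetic generator of pattern-class images and capture metadata are
    included so the full pipeline is testable without field photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
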