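Package: corcmp
Title: Statistical Comparison of Two Pearson Correlations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Significance tests and confidence intervals for the difference
    between two Pearson product-moment correlations: correlations measured in
    two independent groups, and dependent (correlated) correlations from a
    single group that either share one variable (overlapping) or share none
    (nonoverlapping).  Implements the classical z and t tests of Pearson and
    Filon, Fisher, Hotelling, Williams, Olkin, Dunn and Clark, Hendrickson,
    Steiger, Meng, Hittner, Raghunathan and Silver, together with Zou's (2007)
    confidence intervals for all three cases, a raw-data front end with a
    variable-pair formula interface, a command-line entry point, and a Monte
    Carlo harness for type-I-error and power calibration of every test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
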