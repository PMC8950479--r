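Package: honeytrace
Title: Trace-Element Quantification, Method Validation and Botanical
    Classification of Unifloral Honeys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-element ICP-MS analysis of honey: two-level
    factorial optimization of acid microwave digestion with pure-error
    significance testing, analytical method validation (Currie detection
    limits, Horwitz precision acceptance, spike-recovery bias tests,
    digestion efficiency), conversion of instrument signals to sample
    concentrations, and botanical-origin classification of unifloral
    honeys from their elemental signatures by principal component and
    linear discriminant analysis with cross-validation and permutation
    testing. Includes a synthetic-data generator reproducing the
    censored, right-skewed, block-correlated structure of honey
    trace-element tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
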