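Package: vaxequity
Title: Composite Equity Assessment of Childhood Immunization Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures equity in childhood vaccination coverage from
    child-level survey records. Ranks children by a composite direct-unfairness
    index (the predicted coverage from a logistic model of fair and unfair
    sources of variation), and computes Wagstaff and Erreygers concentration
    indices, absolute equity gaps, equity levels, confidence bounds and
    concentration curves against either that composite ranking or a wealth-only
    ranking built by principal-component analysis of household assets. A
    regression decomposition attributes the concentration index to signed
    factor shares. Includes schedule-aware outcome derivation (per-dose,
    zero-dose, fully-immunized-for-age, complete), a synthetic survey
    generator with planted inequity for validation, and a column-mapping
    reader for DHS-style child-recode exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
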