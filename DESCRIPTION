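Package: seqmetabias
Title: Sequential Decision and Design Biases in Cumulative Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the biases that arise in accumulating (cumulative or
    sequential) meta-analysis when the results of earlier trials are used to
    decide whether to run the next trial (sequential decision bias) or to set
    its sample size (sequential design bias). Provides fixed-effect
    inverse-variance pooling, probability-of-next-trial models (power-law,
    extreme-value, probit, and a power-calculation window rule), closed-form
    and quadrature bias decompositions, truncated-normal stopped-trial
    expectations, a seeded Monte-Carlo engine for decision- and design-bias
    simulation studies, and a packaged worked example based on a fluoride
    dentifrice meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
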