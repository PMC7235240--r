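Package: cq2f
Title: Diagnostics for Reverse-Transcription Bias in Nested qPCR Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design, simulate and analyse nested reverse-transcription
    (RT) and qPCR titration experiments. Implements the Cq2f dilution-response
    statistic (the Cq increase per 2-fold dilution of input, ideally 1) along
    both the RT and the qPCR axes, replicate condensation by the best-duplicate
    rule, negative-control quality checks, delta-delta-Cq relative
    quantification with dose-dependence and RNA-fragmentation artifact
    analyses, and a generative Cq simulator with hyperbolic RT saturation so
    the whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
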