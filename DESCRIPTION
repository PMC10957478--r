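Package: hetfx
Title: Heterogeneous Treatment Effects of AI Assistance in Multi-Reader
    Diagnostic Studies
Version: 0.1.0
Authors@R:
    person("hetfx", "maintainers", email = "hetfx@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for heterogeneous treatment effects of AI
    assistance on radiologists in multi-reader multi-case (MRMC) studies.
    Provides empirical Bayes shrinkage of per-reader effect estimates,
    split-sampling regression designs that are immune to reversion to the
    mean, attenuation-bias (errors-in-variables) correction via the
    reliability ratio, ordinary least squares with two-way (case by
    reader) cluster-robust covariance, subgroup and AI-error-bin
    analyses, and a synthetic reader-study generator with known ground
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
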