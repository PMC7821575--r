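Package: thoughtnet
Title: Multi-Block Factor Analysis and Network-Based Statistics for
    Repeated-Measures Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating the content of self-generated thought,
    measured by repeated post-scan questionnaires, to whole-brain
    functional connectivity within individuals.  Implements multiple
    factor analysis (MFA) for multi-block questionnaire data with a
    nested day-by-run normalization, bootstrap confidence intervals for
    factor contributions, construction of vectorized connectivity
    stacks from ROI time series, and a repeated-measures network-based
    statistic (NBS) using an edge-wise general linear model with
    Freedman-Lane permutation constrained to within-subject
    exchangeability blocks.  A synthetic-data generator with planted
    latent thought factors and a planted subnetwork supports power
    analysis and end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
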