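Package: emanet
Title: Temporal Network Analysis of Twice-Daily Experience-Sampling Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring, reliability and two-step multilevel vector-autoregression
    (VAR) network estimation for ecological momentary assessment (EMA) panels
    sampled twice a day (morning and afternoon). Provides readers and writers
    for long-format EMA panels and trial-level Go/No-go logs, composite
    scoring with reverse coding, compliance and descriptive summaries,
    Cronbach's alpha and odd/even-day Spearman-Brown reliability, node-wise
    multilevel models with person-mean covariates and random lag-1 slopes
    producing temporal, contemporaneous and between-person partial-correlation
    networks, false-discovery-rate edge selection with the "or" rule, and a
    synthetic-study generator with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
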