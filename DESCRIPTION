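Package: turnfto
Title: Turn-Timing Analysis of Dyadic Conversation via Floor Transfer Offsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of turn-taking in dyadic
    conversation. Reads two-speaker speech/silence annotations (Praat TextGrid
    or interval CSV), enforces a minimum-silence rule, extracts talkspurts and
    floor transfers, computes signed Floor Transfer Offsets (FTO), classifies
    transitions (gaps, between-speaker overlaps, within-speaker overlaps) and
    perceptual categories (smooth, gap/overlap, long gap/overlap), and
    summarises timing by dyad, group and conversational context. Fits Bayesian
    multilevel ex-Gaussian regressions of FTO with dyad-level random intercepts
    and context slopes via JAGS, including separate gaps-only and overlaps-only
    models, posterior contrasts with a robustness criterion, and posterior
    predictive checks. A synthetic-conversation generator with full ground
    truth makes every pipeline stage testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    rjags,
    coda,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
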