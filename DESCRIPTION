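Package: panelkappa
Title: Agreement Analysis for Ordinal Cancer-Grading Reader Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for blinded-validation reader studies of ordinal cancer
    grading, modelled on multi-rater evaluations of prostate biopsy ISUP
    grade groups. Implements quadratically weighted Cohen's kappa on the
    six-level benign/GG1-GG5 scale, benign-versus-cancer detection metrics
    with representative-rater selection by median balanced accuracy,
    consensus reference-standard construction (two reviewers plus an
    adjudicator, and panel majority votes), two-sided permutation tests
    comparing rater groups, a crossed rater-by-case bootstrap for
    confidence intervals, ordinal median ensembling, leaderboard timeline
    summaries, and a synthetic rater-panel generator with closed-form
    agreement oracles for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
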