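Package: habitseq
Title: Analysis of App-Based Motor Sequence Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying motor sequence learning, automaticity,
    reward sensitivity and practice timing from per-trial keystroke logs of
    a month-long app-based training study. Provides per-participant
    exponential-decay models of movement time and of inter-keystroke-interval
    consistency, trial-to-trial reward-sensitivity statistics summarised by
    conditional Gaussian distributions, circular statistics of diurnal
    practice times (Rayleigh and Watson two-sample U2 tests), a group-level
    inference layer (Kruskal-Wallis, three-way mixed ANOVA, paired t-tests,
    Benjamini-Hochberg FDR), and a synthetic keystroke-log generator with
    known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
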