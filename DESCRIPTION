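Package: infotrans
Title: Information Transmission from Text Stimuli to Individual Raters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much information text stimuli transmit to
    individual raters. Scores texts by cumulated empirical entropy and
    semantic diversity, fits each participant's perceived-information
    ratings as a no-intercept ridge regression on stimulus entropy
    (external factor) and Big Five personality traits (internal factors),
    decomposes the fit into relative regressor contributions to obtain a
    per-person information-sensitivity index, and relates that index to
    boredom and to cohort membership (e.g. healthy controls versus ADHD
    outpatients). Includes a synthetic stimulus-and-cohort generator with
    a controlled entropy gradient, exact small-sample nonparametric tests,
    Fisher-z confidence intervals with Bonferroni control, and an
    end-to-end pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
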