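Package: osascore
Title: Online Societal Association Scoring for Social-Media Accounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the online societal association (OSA) of social-media
    accounts during a health crisis from their tweet streams. The composite
    is the product of impact-weighted daily engagement, a signed
    majority-class sentiment strength, and an inclusivity-and-diversity
    strength based on community-keyword usage, normalized within user
    groups (political leaders, health organizations). Includes parsers for
    Twitter-API-v2-shaped JSON Lines and a flat CSV dialect, an engagement
    smoothing chain (exponential moving average, z-score outlier removal,
    Savitzky-Golay filtering), hashtag and mention frequency tables, and a
    seeded synthetic-cohort generator for validation.
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
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
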