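Package: prrlife
Title: Post-Reproductive Lifespan and Representation from Longitudinal
    Life-History Records
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies post-reproductive lifespan in long-lived animal
    populations from longitudinal individual life-history records subject
    to left truncation (delayed entry) and right censoring. Provides
    age-specific exposure and fecundity schedules, nonparametric
    delayed-entry survivorship (product-limit or Breslow), person-years
    lived after a given age, the post-reproductive representation (PrR)
    statistic with a permutation significance test, propagation of
    age-estimation uncertainty by resampling, the mean-plus-two-SD
    successful-interbirth-interval criterion for classifying individual
    females as post-reproductive, and an individual-based life-history
    simulator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
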