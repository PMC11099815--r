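Package: emawear
Title: Wearable Sleep, Heart-Rate Variability and Ecological Momentary
    Assessment Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives validity-filtered sleep and heart-rate-variability
    features from wrist-worn device streams (minute activity, 5-second
    pulse rate, in-bed records), links them to momentary sleepiness, mood
    and energy ratings collected by ecological momentary assessment (EMA)
    and to stress and well-being questionnaires, and analyses the linked
    table with quartile-based nonparametric group comparisons
    (Mann-Whitney U, Bonferroni, effect sizes) and person-mean-centered
    linear mixed models with forward stepwise AIC selection. Ships a
    synthetic-cohort generator with a documented ground-truth
    parameterization so the whole pipeline is testable without access to
    any device export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
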