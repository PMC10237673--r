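Package: mateguard
Title: Cost-Benefit Modelling and Estimation Statistics for Drosophila
    Mating-Duration Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying experience-dependent shortening of mating
    duration (SMD) in male Drosophila melanogaster. Implements a marginal-
    value-theorem cost-benefit model of post-ejaculatory mate guarding
    (optimal guarding time, parameter-regime classification, comparative-
    statics scenarios), seeded generators for synthetic behavioral assay
    data (mating duration, courtship, locomotion, fecundity, two-sire
    paternity crosses, activity-reporter fluorescence), and the statistical
    pipeline applied to such assays: inclusion filtering, percent-reduction
    effect sizes, Student's t, Lilliefors-corrected normality checks,
    Kruskal-Wallis with Dunn's post-hoc comparisons, bootstrap estimation
    statistics, significance annotation, and egg/progeny/paternity-share
    accounting with a recessive eye-color marker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
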