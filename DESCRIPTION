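Package: ghbsa
Title: Analysis of Voluntary Oral GHB Self-Administration Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for phenotyping voluntary oral
    gamma-hydroxybutyric acid (GHB) self-administration in rats:
    two-bottle-choice home-cage intake quantification (daily dose in mg/kg,
    drug preference, intake area under the curve, binge detection),
    deterministic replay of operant conditioning event logs under fixed-ratio,
    progressive-ratio, non-reinforced and quinine-adulterated schedules,
    Belin-style addiction-severity classification (z-scored measures,
    three-of-four combination sums, top-quartile flags, consistency counts),
    novel-object-recognition and elevated-plus-maze scoring from tracking
    data, and the study-defined statistics (Bonferroni-corrected correlation
    set, baseline-anxiety regression). A synthetic-cohort simulator generates
    every input table the pipeline consumes, so the whole analysis is
    exercisable end to end without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
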