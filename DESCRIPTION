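Package: iflt
Title: Integrated Food Literacy Tool: Screener Scoring, Goal Prioritization and Validation
Version: 0.1.0
Authors@R:
    person("IFLT", "Maintainers", email = "iflt@example.org", role = c("aut", "cre"))
Description: Implements a 17-item food-literacy screener scored on a 0-100
    scale, an algorithm that prioritizes 24 food-literacy goals to individual
    needs by combining per-answer item priority scores with expert ranking
    weights, and the validation machinery around it: content validity indices
    (I-CVI and S-CVI), the Flesch reading-ease formula, psychometric
    statistics (Pearson construct validity, Cronbach's alpha, test-retest
    reliability with an absolute-agreement intraclass coefficient,
    independent t-tests), and an accuracy evaluation of eating-goal
    assignment against food-frequency-questionnaire intake thresholds.
    A synthetic-cohort generator with a latent food-literacy trait makes the
    whole pipeline exercisable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
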