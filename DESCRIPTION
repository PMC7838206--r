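Package: pavca
Title: Pavlovian Conditioned Approach Phenotyping and Cocaine Conditioning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores Pavlovian conditioned approach (PavCA) behavior from
    trial-level operant event logs, classifies rats as sign-trackers,
    goal-trackers or intermediates from the terminal PavCA index, and scores
    conditioned reinforcement (incentive value of a reward cue), cocaine
    conditioned cue preference and cocaine contextual conditioning sessions.
    Includes the accompanying inferential battery (mixed repeated-measures
    ANOVA with classical eta squared, Tukey HSD, Pearson correlations with
    r squared, and principal components with Kaiser-normalized varimax
    rotation) and a latent-trait synthetic cohort generator with configurable
    correlation between incentive salience and cocaine responsivity, so the
    full pipeline can be exercised and power-tested without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
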