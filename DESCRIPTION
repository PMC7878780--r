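Package: metsmarkov
Title: Six-State Continuous-Time Markov Modelling of Metabolic Syndrome
    Progression and Cardiovascular Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the natural history of metabolic syndrome
    from panel-observed screening data. Subjects are staged by a refined
    metabolic classification (free of metabolic disorder, mild metabolic
    disorder, metabolic syndrome) built from the five harmonized criteria,
    and their progression to cardiovascular disease, cardiovascular death
    and other-cause death is described by a six-state continuous-time
    Markov model with proportional-hazards age and sex effects on the
    transition intensities. Includes maximum-likelihood estimation for
    interval-censored panel states combined with exactly-dated registry
    events, likelihood-ratio model comparison, cumulative-risk prediction,
    and a synthetic-cohort simulator for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
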