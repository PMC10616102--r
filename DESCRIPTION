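Package: trustmrt
Title: Generative Modelling and Longitudinal Analysis of Multi-Round Trust Game Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing behaviour in the 10-round investor-trustee trust
    game. Implements an interactive partially observable Markov decision process
    (I-POMDP) model of investment behaviour with Fehr-Schmidt style inequality
    aversion, social risk aversion, level-k theory of mind, finite-horizon
    planning, and an irritability mechanism that mixes in a retaliatory policy
    after below-expectation partner actions. Subject-level parameters are
    estimated by exhaustive grid search over a discrete parameter space and
    model variants are compared with a Draper Bayesian information criterion.
    Also provides model-free behavioural trust indices, a synthetic-cohort
    generator for parameter-recovery and power studies, within/between-person
    age decomposition, principal-component adversity scoring, and longitudinal
    linear mixed-model stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'game-core.R'
    'agents.R'
    'inference.R'
    'behavior-metrics.R'
    'synthetic-cohort.R'
    'longitudinal-stats.R'
    'interface.R'
    'trustmrt-package.R'
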