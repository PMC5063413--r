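Package: forgetfulRL
Title: Temporal-Difference Learning with Value Decay in Self-Paced Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates temporal-difference (TD) learning agents whose learned
    action or state values decay multiplicatively at every time step
    (forgetting), in self-paced goal-reaching tasks: a linear track with
    optional backward moves and mid-track rewards, a cost-benefit T-maze, and
    a kinematic T-maze with continuous position loosely coupled to internal
    states. Supports Q-learning and SARSA reward-prediction errors, softmax
    action selection, and simulated dopamine-blockade manipulations that
    scale the prediction-error-dependent value increment. Also provides a
    reduced two-variable continuous-time model of the Go/Stay value contrast
    with equilibrium finding, stability classification and saddle-node
    bifurcation detection, exact chance-level trial lengths from
    absorption-time analysis, and seeded, config-driven experiment drivers
    with tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
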