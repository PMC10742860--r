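Package: shidr
Title: Delayed Impulsive Rumor-Propagation Dynamics with Saturated Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.com", role = c("aut", "cre"))
Description: Simulate and analyse a susceptible-hesitant-infected-refuting-
    recovered (SHIDR) rumor-spreading model with a discrete delay, saturated
    (psychological) incidence, and periodic impulsive "vaccination" pulses that
    model repeated popular-science education. Provides closed-form threshold
    quantities (two reproduction numbers, the critical pulse proportion, the
    rumor-free periodic susceptible solution, and a permanence floor), a
    fixed-step Runge-Kutta method-of-steps integrator for impulsive delay
    differential systems, long-run classification of trajectories (rumor
    extinction versus permanence), threshold parameter sweeps, and packaged
    numerical-experiment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
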