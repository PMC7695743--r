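Package: pursuitkin
Title: Kinematic Analysis and Modelling of Aerial Pursuit Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-dimensional pursuit trajectories of a
    flying pursuer chasing a moving target, as recorded by high-speed stereo
    videography of chasing insects. Extracts heading (line-of-flight), bearing
    (line-of-sight) and error angles and their rates from position tracks,
    summarises angular distributions with circular statistics, simulates
    closed-loop pure, biased, proportional-navigation and mixed pursuit
    steering controllers with sensorimotor delays, identifies control-law
    gains and delays by lag-scanned linear fits, and evaluates candidate
    controllers by replaying them against recorded chases with a
    trajectory-error metric, grid search over gains, and ANOVA-based strategy
    comparison. A synthetic-chase generator with known ground-truth
    controllers supports parameter-recovery experiments without recorded
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
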