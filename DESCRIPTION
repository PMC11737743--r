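Package: shapesim
Title: Simulation and Analysis of Automatic Behavior-Shaping Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyzes operant behavior-shaping experiments in
    which a hidden target must be located by clicking on a blank screen while
    a reinforcement window contracts toward the target according to a
    parametric shaping function. Provides the exponential shaping-function
    family with its linear limit, a deterministic (seeded) trial and session
    engine, synthetic win-stay/shift participant agents with between-subject
    heterogeneity, the two standard outcome measures (loess-smoothed
    accumulation area under the target-click trajectory, and total clicks per
    trial), and the matching inference layer: a random-intercept Gaussian
    mixed model with variance partitioning for accumulation area, and a
    negative-binomial regression with incidence rate ratios and
    overdispersion diagnostics for click counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
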