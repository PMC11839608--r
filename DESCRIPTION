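Package: apeo
Title: Adaptive Physical Education Optimization with EEG-Informed Closed-Loop Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-loop simulator for EEG-informed adaptive physical
    education programmes. Generates synthetic participant cohorts and
    band-limited EEG traces, extracts theta/alpha/beta band powers and the
    theta/alpha ratio, classifies affective state with a rule engine and maps
    states to activity adjustments, evolves participant fitness, engagement
    and adherence under PID control and disturbances, personalises activity
    intensity, duration and modality with tabular Q-learning at the
    individual and group level, models gamified rewards, engagement decay,
    social-influence graphs and real-time feedback with fatigue gating, and
    includes a small from-scratch recurrent network for engagement
    prediction. All components are deterministic for a fixed seed and ship
    with closed-form and oracle-based tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
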