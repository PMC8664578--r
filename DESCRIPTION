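Package: nremtools
Title: NREM Sleep Event Detection, Slow-Wave Coherence and
    Sleep-Dependent Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of NREM sleep events (slow
    waves, delta waves, slow and fast sleep spindles) from multi-channel
    scalp EEG, slow-wave-triggered multitaper coherence across electrode
    pairs, sleep architecture and non-parametric circadian rhythm
    analysis of actigraphy, scoring of the motor sequence task, and a
    statistical pipeline linking NREM microarchitecture to overnight
    motor memory consolidation (covariance comparison via Box's M,
    principal components with forward stepwise regression, and linear
    mixed models with backward elimination and marginal means). Includes
    a synthetic polysomnography generator with planted ground-truth
    events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
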