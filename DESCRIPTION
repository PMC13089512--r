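Package: remfrag
Title: Analysis of Experimentally Fragmented REM Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the consequences of fragmenting rapid eye movement
    (REM) sleep with sensory stimulation. Implements sleep-macrostructure scoring and
    the REM fragmentation index, Markov stage-transition matrices with paired
    between-condition comparison, stimulation-locked epoch selection, Morlet-wavelet
    event-related spectral perturbation (ERSP) with decibel baseline correction,
    cluster-based Monte Carlo permutation inference over time-frequency maps and scalp
    topographies (including topography-behaviour correlation), trial-level autonomic
    reactivity (inter-beat-interval artifact correction, heart-rate deceleration,
    electrodermal pre-processing and a continuous-decomposition skin-conductance
    statistic), recognition-memory sensitivity (d-prime) with boundary corrections,
    and the mixed-model planned-contrast scheme tying them together. A synthetic
    cohort generator with planted ground truth exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils,
    lme4,
    lmerTest,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
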