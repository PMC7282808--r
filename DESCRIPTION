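Package: statemap
Title: Hidden-State Inference Models of Hippocampal Place-Field Remapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A Bayesian nonparametric account of hippocampal place-field
    remapping as hidden state inference. Provides the Chinese Restaurant
    Process prior over partitions of observations, conjugate
    normal-Wishart Gaussian and numerically marginalized Von Mises
    observation models, partition and state evidence ratios, rotational
    reference-direction inference for cue-rotation designs, a
    Beta-distribution population model of per-cell rate-modulation
    extents, and a suite of reproducible simulation protocols that map
    experimental remapping paradigms (cue constellations, experience-
    dependent remapping, map stabilization, directional foraging, cue
    rotation, morph environments, training-schedule and cue-variability
    manipulations) onto tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
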